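# Randomization schemes: ordered codon-slot templates parsed from primer
# strings, per-library diversity arithmetic and in-silico library sampling.

.placeholder_mix <- c("111" = "mix1", "222" = "mix2", "333" = "mix3")

fixed_slot <- function(codon, partial = nchar(codon) < 3L) {
  list(kind = "fixed", codon = codon, partial = partial)
}
randomized_slot <- function(mix) list(kind = "randomized", mix = mix)

#' Parse a randomized primer into codon slots
#'
#' Tokenizes a whitespace-delimited primer string in which the placeholder
#' triplets \code{111}, \code{222} and \code{333} mark codon slots randomized
#' with trinucleotide mixes 1-3 and all other tokens are plain DNA.
#' Consecutive DNA tokens are merged into one fixed run (the whitespace in
#' the printed primers is cosmetic) and each run is split into codon-sized
#' fixed slots. A run immediately followed by a randomized slot is split from
#' its right edge so that its end stays in frame with the placeholder;
#' otherwise it is split from the left. Leftover bases at run edges become
#' partial fixed slots (fewer than 3 bases), which carry sequence but no
#' codon identity.
#'
#' @param primer Primer string, 5' to 3'; whitespace-delimited tokens.
#' @param frame Number of leading bases of the first fixed run set aside as a
#'   partial slot before triplet splitting (default 0).
#' @return An object of class \code{sy_slots}: an ordered list of slots, each
#'   either \code{list(kind = "fixed", codon, partial)} or
#'   \code{list(kind = "randomized", mix)}.
#' @export
#' @examples
#' s <- parse_randomized_primer(sybody_primer("CDR1_a_b"))
#' sum(vapply(s, function(x) x$kind == "randomized", logical(1))) # 5
parse_randomized_primer <- function(primer, frame = 0) {
  stopifnot(is.character(primer), length(primer) == 1L, frame >= 0, frame < 3)
  tokens <- strsplit(trimws(primer), "\\s+")[[1]]
  if (length(tokens) == 0) return(structure(list(), class = "sy_slots"))
  bad <- tokens[!grepl("^[ACGT]+$", tokens) & !tokens %in% names(.placeholder_mix)]
  if (length(bad) > 0) {
    stop("token is neither DNA nor a mix placeholder: '", bad[1], "'",
         call. = FALSE)
  }
  is_ph <- tokens %in% names(.placeholder_mix)
  # group consecutive DNA tokens into runs
  grp <- cumsum(is_ph | c(TRUE, is_ph[-length(is_ph)]))
  slots <- list()
  first_run <- TRUE
  idx <- split(seq_along(tokens), grp)
  for (g in idx) {
    if (is_ph[g[1]]) {
      slots <- c(slots, list(randomized_slot(.placeholder_mix[[tokens[g[1]]]])))
      next
    }
    run <- paste(tokens[g], collapse = "")
    followed_by_ph <- max(g) < length(tokens) && is_ph[max(g) + 1L]
    off <- 0L
    if (first_run && frame > 0) {
      slots <- c(slots, list(fixed_slot(substr(run, 1L, frame))))
      off <- as.integer(frame)
    }
    first_run <- FALSE
    body <- substr(run, off + 1L, nchar(run))
    rem <- nchar(body) %% 3L
    if (followed_by_ph && rem > 0L) {
      # split from the right: leading partial, then whole codons
      slots <- c(slots, list(fixed_slot(substr(body, 1L, rem))))
      body <- substr(body, rem + 1L, nchar(body))
      rem <- 0L
    }
    n3 <- (nchar(body) - rem) / 3L
    if (n3 > 0) {
      starts <- seq(1L, by = 3L, length.out = n3)
      for (s in starts) {
        slots <- c(slots, list(fixed_slot(substr(body, s, s + 2L))))
      }
    }
    if (rem > 0L) {
      slots <- c(slots, list(fixed_slot(substr(body, nchar(body) - rem + 1L,
                                               nchar(body)))))
    }
  }
  structure(slots, class = "sy_slots", primer = primer)
}

slot_is_randomized <- function(slots) {
  vapply(slots, function(s) s$kind == "randomized", logical(1))
}

#' Count randomized slots in a slot list or scheme
#' @param x An \code{sy_slots} or \code{randomization_scheme} object.
#' @return Integer count of randomized codon slots.
#' @export
n_randomized <- function(x) {
  if (inherits(x, "randomization_scheme")) {
    return(sum(vapply(x$cdrs, n_randomized, integer(1))))
  }
  sum(slot_is_randomized(x))
}

#' @export
print.sy_slots <- function(x, ...) {
  lab <- vapply(x, function(s) {
    if (s$kind == "randomized") paste0("<", s$mix, ">") else s$codon
  }, character(1))
  cat("<sy_slots>", length(x), "slots,", n_randomized(x), "randomized\n")
  cat(paste(lab, collapse = " "), "\n")
  invisible(x)
}

#' Build a library randomization scheme
#'
#' Constructs the codon-slot template of one of the three sybody libraries
#' (\code{concave}, \code{loop}, \code{convex}) from the built-in CDR
#' assembly primers, or from user-supplied primers. The concave scheme also
#' carries the non-randomized framework DNA, enabling full-length member
#' sampling.
#'
#' @param library Library name, or an arbitrary identifier when
#'   \code{primers} is supplied.
#' @param primers Optional named character vector of primer strings (names
#'   become CDR labels, e.g. \code{c(CDR1 = "...", ...)}).
#' @param framework Optional framework DNA string; defaults to the built-in
#'   concave framework for \code{library = "concave"}.
#' @param renormalization Passed to \code{\link{mix_definition}}.
#' @return A \code{randomization_scheme}: list with \code{library_name},
#'   \code{cdrs} (named list of \code{sy_slots}), \code{mixes} and
#'   \code{framework} (string or \code{NA}).
#' @export
#' @examples
#' sch <- randomization_scheme("concave")
#' n_randomized(sch) # 15
randomization_scheme <- function(library, primers = NULL, framework = NULL,
                                 renormalization = "proportional") {
  if (is.null(primers)) {
    if (!library %in% names(.sybody_scheme_primers)) {
      stop("unknown library: '", library,
           "' (expected concave, loop or convex)", call. = FALSE)
    }
    primers <- vapply(.sybody_scheme_primers[[library]], sybody_primer,
                      character(1))
    if (is.null(framework) && library == "concave") {
      framework <- sybody_framework("concave")
    }
  }
  cdrs <- lapply(primers, parse_randomized_primer)
  if (is.null(names(cdrs)) || any(names(cdrs) == "")) {
    names(cdrs) <- paste0("CDR", seq_along(cdrs))
  }
  mixes <- lapply(stats::setNames(nm = c("mix1", "mix2", "mix3")),
                  mix_definition, renormalization = renormalization)
  structure(list(library_name = library, cdrs = cdrs, mixes = mixes,
                 framework = if (is.null(framework)) NA_character_ else framework),
            class = "randomization_scheme")
}

#' @export
print.randomization_scheme <- function(x, ...) {
  cat("<randomization_scheme>", x$library_name, "-",
      n_randomized(x), "randomized slots\n")
  for (nm in names(x$cdrs)) {
    cat(sprintf("  %s: %d slots (%d randomized)\n", nm, length(x$cdrs[[nm]]),
                n_randomized(x$cdrs[[nm]])))
  }
  if (!is.na(x$framework)) cat("  framework:", nchar(x$framework), "nt\n")
  invisible(x)
}

#' Exact theoretical amino-acid diversity of a scheme
#'
#' The number of distinct amino-acid sequences a randomization scheme can
#' encode: the product, over randomized codon slots, of the number of amino
#' acids with nonzero probability in the slot's mix. Fixed slots contribute a
#' factor of 1. Computed exactly (arbitrary precision); report with
#' \code{\link{diversity_signif}} or \code{format()}.
#'
#' @param scheme A \code{randomization_scheme} (or a single \code{sy_slots}
#'   list plus \code{mixes}).
#' @param mixes Named list of mixes when \code{scheme} is a raw slot list.
#' @return An exact integer of class \code{sy_bigint}.
#' @export
#' @examples
#' d <- theoretical_diversity(randomization_scheme("concave"))
#' diversity_signif(d) # 8.3e17
theoretical_diversity <- function(scheme, mixes = NULL) {
  if (inherits(scheme, "randomization_scheme")) {
    slots <- do.call(c, lapply(scheme$cdrs, unclass))
    mixes <- scheme$mixes
  } else {
    slots <- scheme
    if (is.null(mixes)) {
      mixes <- lapply(stats::setNames(nm = c("mix1", "mix2", "mix3")),
                      mix_definition)
    }
  }
  supports <- vapply(slots, function(s) {
    if (s$kind != "randomized") return(1L)
    mix_support(mixes[[s$mix]])
  }, integer(1))
  big_prod(supports)
}

#' Diversity rounded to significant figures
#' @param d An \code{sy_bigint} from \code{\link{theoretical_diversity}}.
#' @param digits Significant figures (default 2, the reporting convention).
#' @return A numeric value, e.g. \code{8.3e17}.
#' @export
diversity_signif <- function(d, digits = 2) big_signif_num(d, digits)

#' Single-codon back-translation table
#'
#' One codon per amino acid (the most frequently used E. coli codon),
#' backing the in-silico realization of trimer-phosphoramidite synthesis,
#' which inserts exactly one codon per amino acid.
#'
#' @param file Optional 2-column CSV (\code{aa,codon}) overriding the
#'   default table.
#' @return Named character vector mapping one-letter amino-acid codes to
#'   codons.
#' @export
default_codon_table <- function(file = NULL) {
  tab <- c(A = "GCG", C = "TGC", D = "GAT", E = "GAA", F = "TTT", G = "GGC",
           H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAC",
           P = "CCG", Q = "CAG", R = "CGT", S = "AGC", T = "ACC", V = "GTG",
           W = "TGG", Y = "TAT")
  if (!is.null(file)) {
    x <- utils::read.csv(file, stringsAsFactors = FALSE)
    if (!all(c("aa", "codon") %in% names(x))) {
      stop("codon table file needs columns 'aa' and 'codon'", call. = FALSE)
    }
    tab[x$aa] <- toupper(x$codon)
  }
  tab
}

# Locate each CDR's randomized codon positions within the framework by
# matching the primer-derived pattern (fixed codons literal, randomized
# slots wild). Fixed bases that belong to primer tails rather than the
# framework are trimmed from the pattern edges until a unique match is found.
locate_randomized_windows <- function(framework, slots) {
  elems <- lapply(slots, function(s) {
    if (s$kind == "randomized") list(wild = TRUE, len = 3L)
    else list(wild = FALSE, seq = s$codon, len = nchar(s$codon))
  })
  # flatten to per-character wildcard mask
  chars <- unlist(lapply(elems, function(e) {
    if (e$wild) rep(NA_character_, 3L) else strsplit(e$seq, "")[[1]]
  }))
  build_pattern <- function(v) {
    paste(ifelse(is.na(v), "[ACGT]", v), collapse = "")
  }
  lo <- 1L; hi <- length(chars)
  repeat {
    if (hi - lo + 1L < 6L) stop("CDR pattern does not match framework",
                                call. = FALSE)
    pat <- build_pattern(chars[lo:hi])
    m <- gregexpr(pat, framework, perl = TRUE)[[1]]
    if (m[1] != -1 && length(m) == 1L) break
    if (m[1] != -1 && length(m) > 1L) {
      stop("CDR pattern matches framework ambiguously", call. = FALSE)
    }
    # trim one fixed base from whichever edge is fixed
    if (!is.na(chars[lo])) lo <- lo + 1L
    else if (!is.na(chars[hi])) hi <- hi - 1L
    else stop("CDR pattern does not match framework", call. = FALSE)
  }
  match_start <- as.integer(m[1])
  # walk the retained characters to locate randomized triplet starts
  pos <- match_start
  out <- integer(0)
  i <- lo
  while (i <= hi) {
    if (is.na(chars[i])) {
      out <- c(out, pos)
      pos <- pos + 3L
      i <- i + 3L
    } else {
      pos <- pos + 1L
      i <- i + 1L
    }
  }
  out # framework start positions of randomized codons, in slot order
}

#' Sample in-silico library members
#'
#' Draws library members from a randomization scheme: each randomized codon
#' slot receives an amino acid drawn independently from its trinucleotide
#' mix, back-translated through a one-codon-per-amino-acid table. When the
#' scheme carries a framework (concave), full-length members are returned
#' with the sampled codons spliced into the framework CDR windows; otherwise
#' the concatenated CDR cassettes are returned.
#'
#' @param scheme A \code{randomization_scheme}.
#' @param n Number of members (>= 0).
#' @param seed Integer seed; sampling is reproducible per seed.
#' @param codon_table Named codon vector, see \code{\link{default_codon_table}}.
#' @param full_length Splice into the framework when available (default).
#' @return A list with \code{dna} (\code{DNAStringSet}), \code{protein}
#'   (\code{AAStringSet}) and \code{members} (data.frame of sampled
#'   amino acids per slot).
#' @export
sample_library <- function(scheme, n, seed, codon_table = default_codon_table(),
                           full_length = !is.na(scheme$framework)) {
  stopifnot(inherits(scheme, "randomization_scheme"))
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  all_slots <- do.call(c, lapply(scheme$cdrs, unclass))
  rand_idx <- which(slot_is_randomized(all_slots))
  k <- length(rand_idx)
  aa_mat <- matrix(character(0), nrow = n, ncol = k)
  if (n > 0 && k > 0) {
    for (j in seq_len(k)) {
      mix <- scheme$mixes[[all_slots[[rand_idx[j]]]$mix]]
      aa_mat[, j] <- sample(names(mix$frequencies), n, replace = TRUE,
                            prob = mix$frequencies)
    }
  }

  pos <- NULL
  if (full_length && !is.na(scheme$framework)) {
    pos <- unlist(lapply(scheme$cdrs, function(sl)
      locate_randomized_windows(scheme$framework, sl)))
    stopifnot(length(pos) == k)
  }

  make_dna <- function(aas) {
    if (!is.null(pos)) {
      fw <- scheme$framework
      for (j in seq_len(k)) {
        substr(fw, pos[j], pos[j] + 2L) <- codon_table[[aas[j]]]
      }
      fw
    } else {
      jj <- 0L
      paste(vapply(all_slots, function(s) {
        if (s$kind == "fixed") return(s$codon)
        jj <<- jj + 1L
        codon_table[[aas[jj]]]
      }, character(1)), collapse = "")
    }
  }

  dna <- vapply(seq_len(n), function(i) make_dna(aa_mat[i, ]), character(1))
  if (n == 0) dna <- character(0)
  # translate complete-codon stream; cassette partial edge bases are trimmed
  trimmed <- substr(dna, 1L, nchar(dna) - nchar(dna) %% 3L)
  prot <- if (n > 0) {
    as.character(Biostrings::translate(Biostrings::DNAStringSet(trimmed)))
  } else character(0)

  nm <- sprintf("%s|member=%d|seed=%d", scheme$library_name, seq_len(n),
                as.integer(seed))
  members <- as.data.frame(aa_mat, stringsAsFactors = FALSE)
  if (k > 0) colnames(members) <- paste0("slot", seq_len(k))
  list(dna = Biostrings::DNAStringSet(stats::setNames(dna, nm)),
       protein = Biostrings::AAStringSet(stats::setNames(prot, nm)),
       members = members)
}
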
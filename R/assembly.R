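# Type IIS digestion / sticky-end ligation simulator.
#
# Conventions: all substrates are linear double-stranded DNA given as the
# top strand 5'->3'. A digest fragment stores the top-strand sequence of its
# full extent plus the lengths of its 5'-protruding single-strand ends
# (`left5`: top-strand extension at the left end, `right5`: bottom-strand
# extension at the right end, both written here in top-strand letters).
# Coordinates are 1-based; cuts are "after base i".

.enzyme_registry <- list(
  BsaI  = list(name = "BsaI",  recognition = "GGTCTC",  cut_top = 1L, cut_bottom = 5L),
  BpiI  = list(name = "BpiI",  recognition = "GAAGAC",  cut_top = 2L, cut_bottom = 6L),
  BbsI  = list(name = "BbsI",  recognition = "GAAGAC",  cut_top = 2L, cut_bottom = 6L),
  SapI  = list(name = "SapI",  recognition = "GCTCTTC", cut_top = 1L, cut_bottom = 4L),
  BspQI = list(name = "BspQI", recognition = "GCTCTTC", cut_top = 1L, cut_bottom = 4L)
)

#' Type IIS restriction enzyme definitions
#'
#' Looks up an enzyme in the built-in registry (BsaI, BpiI/BbsI, SapI/BspQI)
#' or builds a custom definition. \code{cut_top}/\code{cut_bottom} are the
#' numbers of bases downstream of the recognition motif at which each strand
#' is cut; their difference is the 5' overhang length (4 for BsaI/BpiI, 3
#' for SapI/BspQI).
#'
#' @param name Enzyme name (registry lookup) or an identifier for a custom
#'   enzyme when \code{recognition} is given.
#' @param recognition,cut_top,cut_bottom Custom cut geometry (optional).
#' @return A \code{restriction_enzyme} list.
#' @export
#' @examples
#' restriction_enzyme("BsaI")$cut_bottom - restriction_enzyme("BsaI")$cut_top # 4
restriction_enzyme <- function(name, recognition = NULL, cut_top = NULL,
                               cut_bottom = NULL) {
  if (is.null(recognition)) {
    e <- .enzyme_registry[[name]]
    if (is.null(e)) stop("unknown enzyme: ", name, call. = FALSE)
  } else {
    stopifnot(grepl("^[ACGT]+$", recognition), cut_top >= 0,
              cut_bottom > cut_top)
    e <- list(name = name, recognition = recognition,
              cut_top = as.integer(cut_top), cut_bottom = as.integer(cut_bottom))
  }
  e$overhang_length <- e$cut_bottom - e$cut_top
  structure(e, class = "restriction_enzyme")
}

as_enzyme <- function(x) {
  if (inherits(x, "restriction_enzyme")) x else restriction_enzyme(x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

new_fragment <- function(seq, left5 = 0L, right5 = 0L) {
  stopifnot(nchar(seq) >= left5 + right5)
  structure(list(seq = seq, left5 = as.integer(left5),
                 right5 = as.integer(right5)),
            class = "digest_fragment")
}

#' @export
print.digest_fragment <- function(x, ...) {
  cat(sprintf("<digest_fragment> %d nt extent | left 5' overhang: %s | right 5' overhang: %s\n",
              nchar(x$seq),
              if (x$left5 > 0) substr(x$seq, 1, x$left5) else "(blunt)",
              if (x$right5 > 0) substr(x$seq, nchar(x$seq) - x$right5 + 1,
                                       nchar(x$seq)) else "(blunt)"))
  invisible(x)
}

#' @export
as.character.digest_fragment <- function(x, ...) x$seq

# overhang strings in top-strand representation
frag_left_ov <- function(f) substr(f$seq, 1L, f$left5)
frag_right_ov <- function(f) substr(f$seq, nchar(f$seq) - f$right5 + 1L,
                                    nchar(f$seq))

#' Reverse-complement a digest fragment
#' @param f A \code{digest_fragment}.
#' @return The fragment viewed from the opposite strand.
#' @export
revcomp_fragment <- function(f) {
  new_fragment(revcomp(f$seq), left5 = f$right5, right5 = f$left5)
}

# cut positions (t = top-strand cut, b = bottom-strand cut, top coordinates)
# for every site of `enzyme` on either strand of `seq`
find_cut_sites <- function(seq, enzyme) {
  L <- nchar(seq)
  hits <- function(motif) {
    m <- gregexpr(motif, seq, fixed = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  }
  cuts <- list()
  for (s in hits(enzyme$recognition)) {       # site on top strand
    e <- s + nchar(enzyme$recognition) - 1L
    cuts <- c(cuts, list(c(t = e + enzyme$cut_top, b = e + enzyme$cut_bottom,
                           site = s)))
  }
  for (s in hits(revcomp(enzyme$recognition))) {  # site on bottom strand
    cuts <- c(cuts, list(c(t = s - 1L - enzyme$cut_bottom,
                           b = s - 1L - enzyme$cut_top, site = s)))
  }
  for (cc in cuts) {
    if (cc[["t"]] < 0L || cc[["b"]] > L) {
      stop("recognition site at position ", cc[["site"]],
           " is too close to the sequence end for a complete cut",
           call. = FALSE)
    }
  }
  if (length(cuts) == 0) return(NULL)
  m <- do.call(rbind, cuts)
  m <- m[order(m[, "t"]), , drop = FALSE]
  if (nrow(m) > 1 && any(m[-1, "t"] < m[-nrow(m), "b"])) {
    stop("overlapping cut sites", call. = FALSE)
  }
  m
}

#' Digest linear DNA with a Type IIS enzyme
#'
#' Scans both strands for the recognition motif and applies every cut
#' (complete digestion). Fragments are returned left to right; a sequence
#' without any site yields a single blunt fragment identical to the input.
#'
#' @param seq DNA (character or \code{DNAString}), linear, top strand.
#' @param enzyme Enzyme name or \code{\link{restriction_enzyme}} object.
#' @return List of \code{digest_fragment}s.
#' @export
#' @examples
#' frags <- digest(paste0(strrep("A", 10), "GGTCTC", strrep("T", 10)), "BsaI")
digest <- function(seq, enzyme) {
  seq <- toupper(as.character(seq))
  stopifnot(grepl("^[ACGT]*$", seq))
  enzyme <- as_enzyme(enzyme)
  cuts <- find_cut_sites(seq, enzyme)
  L <- nchar(seq)
  if (is.null(cuts)) return(list(new_fragment(seq)))
  bounds <- rbind(c(t = 0L, b = 0L), cuts[, c("t", "b"), drop = FALSE],
                  c(t = L, b = L))
  out <- vector("list", nrow(bounds) - 1L)
  for (i in seq_len(nrow(bounds) - 1L)) {
    t0 <- bounds[i, "t"]; b0 <- bounds[i, "b"]
    t1 <- bounds[i + 1L, "t"]; b1 <- bounds[i + 1L, "b"]
    out[[i]] <- new_fragment(substr(seq, t0 + 1L, b1),
                             left5 = b0 - t0, right5 = b1 - t1)
  }
  out
}

#' Ligate two digest fragments
#'
#' Joins \code{a}'s right end to \code{b}'s left end. The ends are compatible
#' when the overhangs have equal length and are complementary (in the
#' top-strand representation used here, when the overhang strings are
#' identical). Digest followed by ligation of the two pieces reconstructs the
#' original sequence exactly.
#'
#' @param a,b \code{digest_fragment}s in compatible orientation (use
#'   \code{\link{revcomp_fragment}} to flip one).
#' @return The joined \code{digest_fragment}.
#' @export
ligate <- function(a, b) {
  stopifnot(inherits(a, "digest_fragment"), inherits(b, "digest_fragment"))
  aov <- frag_right_ov(a)
  bov <- frag_left_ov(b)
  if (a$right5 != b$left5 || aov != bov) {
    stop(sprintf(
      "incompatible overhangs: right end 5'-%s-3' (bottom strand) vs left end 5'-%s-3' (top strand)",
      if (nzchar(aov)) revcomp(aov) else "(blunt)",
      if (nzchar(bov)) bov else "(blunt)"), call. = FALSE)
  }
  new_fragment(paste0(substr(a$seq, 1L, nchar(a$seq) - a$right5), b$seq),
               left5 = a$left5, right5 = b$right5)
}

#' Translate in-frame DNA
#'
#' Standard genetic code translation of a DNA sequence whose length is a
#' multiple of 3.
#'
#' @param dna DNA character or \code{DNAString}.
#' @param trailing_stop \code{"strip"} (default) removes a single trailing
#'   stop codon, \code{"keep"} retains it, \code{"error"} fails on it.
#' @param allow_internal_stop Keep internal stops as \code{*} instead of
#'   failing.
#' @return Protein sequence (character).
#' @export
#' @examples
#' translate_dna("ATGGCGTAA") # "MA"
translate_dna <- function(dna, trailing_stop = c("strip", "keep", "error"),
                          allow_internal_stop = FALSE) {
  trailing_stop <- match.arg(trailing_stop)
  dna <- toupper(as.character(dna))
  if (nchar(dna) == 0) return("")
  if (nchar(dna) %% 3 != 0) {
    stop("sequence length ", nchar(dna), " is not divisible by 3",
         call. = FALSE)
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(dna)))
  has_trailing <- endsWith(aa, "*")
  body <- if (has_trailing) substr(aa, 1, nchar(aa) - 1) else aa
  if (grepl("\\*", body) && !allow_internal_stop) {
    stop("internal stop codon at residue ", regexpr("\\*", body),
         call. = FALSE)
  }
  if (has_trailing) {
    if (trailing_stop == "error") stop("trailing stop codon", call. = FALSE)
    if (trailing_stop == "strip") aa <- body
  }
  aa
}

#' Open-reading-frame report
#'
#' Examines the three forward frames of a sequence and reports the frame
#' giving a stop-free translation (frames tried in order 0, 1, 2; trailing
#' bases that do not complete a codon are ignored).
#'
#' @param seq DNA character, \code{DNAString} or \code{digest_fragment}.
#' @return List with \code{frame}, \code{length_nt}, \code{length_aa},
#'   \code{internal_stop}, \code{protein}.
#' @export
orf_report <- function(seq) {
  seq <- toupper(as.character(seq))
  for (fr in 0:2) {
    body <- substr(seq, fr + 1L, nchar(seq))
    body <- substr(body, 1L, nchar(body) - nchar(body) %% 3L)
    aa <- translate_dna(body, trailing_stop = "strip",
                        allow_internal_stop = TRUE)
    if (!grepl("\\*", aa)) {
      return(list(frame = fr, length_nt = nchar(seq), length_aa = nchar(aa),
                  internal_stop = FALSE, protein = aa))
    }
  }
  list(frame = NA_integer_, length_nt = nchar(seq), length_aa = NA_integer_,
       internal_stop = TRUE, protein = NA_character_)
}

largest_fragment <- function(frags) {
  frags[[which.max(vapply(frags, function(f) nchar(f$seq), numeric(1)))]]
}

#' Two-step Type IIS assembly of a sybody library cassette
#'
#' Simulates the library assembly: the CDR1 cassette is digested with BsaI
#' and the CDR2 cassette with BpiI, the compatible 4-base sticky ends are
#' ligated, then the CDR1-CDR2 product (BsaI) is joined to the CDR3 cassette
#' (BpiI). After each complete digestion the largest fragment (the coding
#' piece; the cut-off primer stubs are ~14 nt) is carried forward. The
#' assembled DNA must contain a single uninterrupted open reading frame.
#'
#' @param cdr1,cdr2,cdr3 Undigested cassette DNA (character or
#'   \code{DNAString}).
#' @param scheme Optional \code{randomization_scheme} used to annotate the
#'   report with the expected randomized-slot count and, when the scheme has
#'   a framework, to check fixed-position identity of the translation.
#' @param enzymes Length-2 character vector: step-1/step-2 enzymes for the
#'   CDR1-side and CDR-side digests (default BsaI, BpiI).
#' @return List with \code{dna} (assembled top strand), \code{orf} (see
#'   \code{\link{orf_report}}) and \code{randomized_slots} (or \code{NA}).
#' @export
assemble_library <- function(cdr1, cdr2, cdr3, scheme = NULL,
                             enzymes = c("BsaI", "BpiI")) {
  stage <- function(id, expr) {
    tryCatch(expr, error = function(e) {
      stop("assembly failed at stage ", id, ": ", conditionMessage(e),
           call. = FALSE)
    })
  }
  f1 <- stage("CDR1-digest", largest_fragment(digest(cdr1, enzymes[1])))
  f2 <- stage("CDR2-digest", largest_fragment(digest(cdr2, enzymes[2])))
  j12 <- stage("CDR1-CDR2-ligation", ligate(f1, f2))
  f12 <- stage("CDR1-CDR2-redigest", largest_fragment(digest(j12$seq, enzymes[1])))
  f3 <- stage("CDR3-digest", largest_fragment(digest(cdr3, enzymes[2])))
  final <- stage("CDR2-CDR3-ligation", ligate(f12, f3))
  orf <- orf_report(final$seq)
  if (orf$internal_stop) {
    stop("assembly failed at stage ORF-check: internal stop codon in every frame",
         call. = FALSE)
  }
  n_rand <- NA_integer_
  if (!is.null(scheme)) {
    n_rand <- n_randomized(scheme)
    if (!is.na(scheme$framework)) {
      fw_prot <- translate_dna(scheme$framework)
      if (nchar(orf$protein) == nchar(fw_prot)) {
        mism <- sum(strsplit(orf$protein, "")[[1]] != strsplit(fw_prot, "")[[1]])
        if (mism > n_rand) {
          stop("assembly failed at stage scaffold-check: ", mism,
               " mismatches to the framework translation exceed the ",
               n_rand, " randomized positions", call. = FALSE)
        }
      }
    }
  }
  list(dna = final$seq, orf = orf, randomized_slots = n_rand)
}

#' Non-randomized concave assembly cassettes
#'
#' Builds the three CDR cassettes of the non-randomized concave scaffold
#' from the built-in framework and the printed assembly-primer tails (BsaI /
#' BpiI sites live on the tails and are cut away during assembly). Their
#' two-step assembly reconstructs the framework DNA exactly, which serves as
#' a round-trip check of the digestion/ligation model.
#'
#' @return Named list of three DNA strings (\code{cdr1}, \code{cdr2},
#'   \code{cdr3}).
#' @export
concave_assembly_fragments <- function() {
  fw <- sybody_framework("concave")
  # CDR1 cassette: framework 5' part + BsaI tail from FW2_a_b_rev
  rc2 <- gsub(" ", "", revcomp(gsub(" ", "", sybody_primer("FW2_a_b_rev"))))
  pref <- longest_prefix_in(rc2, fw)
  cdr1 <- paste0(substr(fw, 1L, pref$end), substr(rc2, pref$len + 1L, nchar(rc2)))
  # CDR2 cassette: BpiI tail (Link1_a_b_for) + framework middle + BsaI tail
  l1 <- gsub(" ", "", sybody_primer("Link1_a_b_for"))
  suf <- longest_suffix_in(l1, fw)
  rc2a <- revcomp(gsub(" ", "", sybody_primer("Link2_a_rev")))
  pref2 <- longest_prefix_in(rc2a, fw)
  cdr2 <- paste0(substr(l1, 1L, nchar(l1) - suf$len),
                 substr(fw, suf$start, pref2$end),
                 substr(rc2a, pref2$len + 1L, nchar(rc2a)))
  # CDR3 cassette: BpiI tail (Link2_a_for) + framework 3' part
  l2 <- gsub(" ", "", sybody_primer("Link2_a_for"))
  suf2 <- longest_suffix_in(l2, fw)
  cdr3 <- paste0(substr(l2, 1L, nchar(l2) - suf2$len),
                 substr(fw, suf2$start, nchar(fw)))
  list(cdr1 = cdr1, cdr2 = cdr2, cdr3 = cdr3)
}

# longest prefix of `x` occurring in `subject`; returns its length and the
# end position of the (first) occurrence
longest_prefix_in <- function(x, subject) {
  for (len in nchar(x):1) {
    p <- substr(x, 1L, len)
    pos <- regexpr(p, subject, fixed = TRUE)
    if (pos != -1) return(list(len = len, start = as.integer(pos),
                               end = as.integer(pos) + len - 1L))
  }
  stop("no prefix of the primer matches the framework", call. = FALSE)
}

longest_suffix_in <- function(x, subject) {
  for (len in nchar(x):1) {
    p <- substr(x, nchar(x) - len + 1L, nchar(x))
    pos <- regexpr(p, subject, fixed = TRUE)
    if (pos != -1) return(list(len = len, start = as.integer(pos),
                               end = as.integer(pos) + len - 1L))
  }
  stop("no suffix of the primer matches the framework", call. = FALSE)
}

#' FX-cloning overhang check
#'
#' Validates a fragment-exchange (FX) cloning insert: the insert must carry
#' SapI/BspQI (GCTCTTC) sites in opposite orientations at its two ends.
#' Returns the two 3-base 5' overhangs produced by digestion, in top-strand
#' representation; a conforming sybody insert yields AGT (5' side) and GCA
#' (3' side).
#'
#' @param insert DNA character or \code{DNAString}.
#' @param enzyme SapI-family enzyme name (default \code{"BspQI"}).
#' @return Named character vector \code{c(left = , right = )}.
#' @export
fx_overhang_check <- function(insert, enzyme = "BspQI") {
  insert <- toupper(as.character(insert))
  enzyme <- as_enzyme(enzyme)
  top <- gregexpr(enzyme$recognition, insert, fixed = TRUE)[[1]]
  bot <- gregexpr(revcomp(enzyme$recognition), insert, fixed = TRUE)[[1]]
  top <- if (top[1] == -1) integer(0) else as.integer(top)
  bot <- if (bot[1] == -1) integer(0) else as.integer(bot)
  if (length(top) == 0 && length(bot) == 0) {
    stop("no ", enzyme$recognition, " site in insert", call. = FALSE)
  }
  if (length(top) != 1L || length(bot) != 1L || top >= bot) {
    stop("insert must carry exactly one ", enzyme$recognition,
         " site per end, in opposite orientations (found ", length(top),
         " forward / ", length(bot), " reverse)", call. = FALSE)
  }
  e <- top + nchar(enzyme$recognition) - 1L
  left <- substr(insert, e + enzyme$cut_top + 1L, e + enzyme$cut_bottom)
  right <- substr(insert, bot - enzyme$cut_bottom, bot - enzyme$cut_top - 1L)
  if (nchar(left) != enzyme$overhang_length ||
      nchar(right) != enzyme$overhang_length) {
    stop("site too close to the insert end for a complete cut", call. = FALSE)
  }
  c(left = left, right = right)
}

#' Wrap an insert with the FX ribosome-display primer tails
#'
#' Adds the Med_FX_for / Med_FX_rev SapI tails around an insert, producing a
#' substrate whose digestion yields the AGT/GCA FX overhangs.
#'
#' @param core Insert DNA placed between the tails.
#' @return DNA character.
#' @export
fx_wrap <- function(core) {
  fwd <- gsub(" ", "", sybody_primer("Med_FX_for"))
  rev <- gsub(" ", "", sybody_primer("Med_FX_rev"))
  paste0(fwd, toupper(as.character(core)), revcomp(rev))
}
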
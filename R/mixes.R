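# Trinucleotide (trimer phosphoramidite) mixes: codon-level randomization
# chemistry that inserts whole codons at defined amino-acid frequencies.
# Cysteine and proline are excluded from all three mixes; no stop codons can
# arise by construction.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.mix1_freq <- local({
  f <- stats::setNames(numeric(20), .AA20)
  f[c("A", "S", "T", "N", "Y")] <- 0.106
  f[c("D", "E", "Q", "R", "K", "H", "W")] <- 0.05
  f[c("F", "M", "V", "I", "L", "G")] <- 0.02
  f # C and P stay at 0; sums to exactly 1
})

.mix_exclusions <- list(
  mix1 = character(0),
  mix2 = c("D", "A"),                      # underrepresented at beta-sheet ends
  mix3 = c("D", "N", "Q", "G", "S", "M")   # rare in the middle of beta-sheets
)

new_trinucleotide_mix <- function(name, frequencies) {
  stopifnot(is.character(name), length(name) == 1L)
  f <- stats::setNames(numeric(20), .AA20)
  f[names(frequencies)] <- frequencies
  if (abs(sum(f) - 1) > 1e-9) {
    stop("mix frequencies must sum to 1 (got ", sum(f), ")", call. = FALSE)
  }
  if (any(f[c("C", "P")] > 0)) {
    stop("C and P must have zero frequency in a trinucleotide mix", call. = FALSE)
  }
  structure(list(name = name, frequencies = f), class = "trinucleotide_mix")
}

#' Trinucleotide mix definitions
#'
#' Returns one of the three amino-acid frequency distributions used at
#' randomized codon slots. Mix 1 is enriched in A, S, T, N, Y (10.6\% each),
#' holds D, E, Q, R, K, H, W at 5\% each and F, M, V, I, L, G at 2\% each.
#' Mix 2 excludes D and A; mix 3 excludes D, N, Q, G, S and M. C and P are
#' excluded from every mix. The distributions for mixes 2 and 3 are obtained
#' from mix 1 by removing the excluded residues and redistributing their
#' probability mass over the remaining ones.
#'
#' @param name One of \code{"mix1"}, \code{"mix2"}, \code{"mix3"}.
#' @param renormalization How the removed probability mass is redistributed:
#'   \code{"proportional"} (default; remaining frequencies scaled by a common
#'   factor) or \code{"uniform"} (equal frequency over the remaining
#'   residues).
#' @return A \code{trinucleotide_mix}: a list with \code{name} and a named
#'   \code{frequencies} vector over the 20 amino acids summing to 1.
#' @export
#' @examples
#' mix_definition("mix1")$frequencies[["A"]]   # 0.106
#' sum(mix_definition("mix3")$frequencies > 0) # 12 permitted residues
mix_definition <- function(name, renormalization = c("proportional", "uniform")) {
  renormalization <- match.arg(renormalization)
  if (!name %in% names(.mix_exclusions)) {
    stop("unknown mix: '", name, "' (expected mix1, mix2 or mix3)", call. = FALSE)
  }
  excluded <- .mix_exclusions[[name]]
  f <- .mix1_freq
  f[excluded] <- 0
  keep <- f > 0
  if (renormalization == "proportional") {
    f[keep] <- f[keep] / sum(f[keep])
  } else {
    f[keep] <- 1 / sum(keep)
  }
  new_trinucleotide_mix(name, f)
}

#' @export
print.trinucleotide_mix <- function(x, ...) {
  nz <- x$frequencies[x$frequencies > 0]
  cat("<trinucleotide_mix>", x$name, "-", length(nz), "amino acids\n")
  print(round(nz, 4))
  invisible(x)
}

# number of amino acids with nonzero probability
mix_support <- function(mix) sum(mix$frequencies > 0)
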
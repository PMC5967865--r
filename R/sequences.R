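# Built-in sequence constants: library-assembly primers and the concave
# framework. Randomized codons are encoded by the placeholder triplets
# 111/222/333, which refer to trinucleotide mixes 1-3.

.sybody_primers <- c(
  CDR1_a_b = "GCA AGC GGT TTC CCG GTG 111 111 111 222 ATG 333 TGG TAT CGT CAG GCA CCG G",
  CDR1_c = "C TGT GCG GCT AGC GGC 111 ATT 111 111 ATC 222 TAC CTG GGC TGG TTT CGC C",
  CDR2_a_b = "GA AGA CCT GTC GCG GCG ATT 111 AGC 111 GGT 111 222 ACG 333 TAC GCA GAT TCT GTT AAG GGC CG",
  CDR2_c = "CGA AGA CCT GCA GCG CTG 111 ACC 111 111 GGT 222 ACC TAC TAC GCG GAC AGC G",
  CDR3_a = "GA AGA CCT GCG GTT TAC TAC TGT 333 GTG 222 GTG GGT 111 222 TAC 333 GGC CAA GGT ACC CAA GTG AC",
  CDR3_b = "CGC GAA GAC CTC GTG AAA GAC 111 GGT 111 111 111 111 111 TAC GAC TAT TGG GGC CAA GGT ACC CAA GTG AC",
  CDR3_c = "GAA GAC CTC TGC GCG GCA GCC 111 111 GGC 111 111 111 CCG CTG 111 111 111 111 TAT 222 TAC TGG GGT CAG GGC ACC CAA GTT ACC GTT TCT",
  FW1_a_b_for = "CAG GTT CAG CTG GTT GAG AGC",
  FW1_a_b_rev = "CAC CGG GAA ACC GCT TGC",
  FW1_c_for = "CAA GTC CAG CTG GTG GAA TCG",
  FW1_c_rev = "GCC GCT AGC CGC ACA G",
  FW2_a_b_rev = "ATG CAT GGT CTC ACG ACC CAC TCA CGT TCT TTG CCC GGT GCC TGA CGA TAC CA",
  FW2_c_rev = "ATG CAT GGT CTC ACT GCG ACG CCC TCA CGC TCT TTG CCC GGT GCC TGG CGA AAC CAG CCC AGG",
  FW3_a_b_for = "CGC AGA TTC TGT TAA GGG CCG",
  FW3_c_for = "ACC TAC TAC GCG GAC AGC G",
  FW4_a_b_rev = "GCT CAC AGT CAC TTG GGT ACC TTG GCC",
  FW4_c_rev = "AGA AAC GGT AAC TTG GGT GCC CTG",
  Link1_a_b_for = "ATG CAT GAA GAC CTG TCG CGG CG",
  Link1_a_b_rev = "ATG CAT GGT CTC ACG ACC CAC",
  Link1_c_for = "TAT ATC GAA GAC CTG CAG CGC TG",
  Link1_c_rev = "ATG CAT GGT CTC ACT GCG ACG",
  Link2_a_for = "TAT ATC GAA GAC CTG CGG TTT ACT ACT G",
  Link2_a_rev = "ATG CAT GGT CTC ACC GCG GTA TCT TCC GGT TTC",
  Link2_b_for = "ATG CAT GGT CTC ACC GCG GTA TCT TCC GGT TTC",
  Link2_b_rev = "ATG CAT GGT CTC ACA CGT TAC AGT AGT AAA CCG CGG",
  Link2_c_for = "ATA TAT GAA GAC CTC TGC GCG GC",
  Link2_c_rev = "ATG CAT GGT CTC AGC AGT AAT ACA AAG CAG TAT CTT CCG G",
  Med_FX_for = "ATA TGC TCT TCT AGT CAG GTT CAG CTG GTT GAG AGC G",
  Med_FX_rev = "TAT AGC TCT TCA TGC GCT CAC AGT CAC TTG GGT ACC",
  Long_FX_for = "ATA TGC TCT TCT AGT CAA GTC CAG CTG GTG GAA TCG",
  Long_FX_rev = "TAT AGC TCT TCA TGC AGA AAC GGT AAC TTG GGT GCC C"
)

.sybody_framework_concave <- paste0(
  "CAGGTTCAGCTGGTTGAGAGCGGTGGTGGCCTGGTCCAAGCTGGCGGTTCGCTGCGTCTGAGCTGCGCCGCAAGCGGTTT",
  "CCCGGTGAGCAGCAGCACGATGACCTGGTATCGTCAGGCACCGGGCAAAGAACGTGAGTGGGTCGCGGCGATTTCCAGCT",
  "CTGGTAGCACCACGACCTACGCAGATTCTGTTAAGGGCCGCTTTACCATCAGCCGCGACAACGCGAAGAATACGGTCTAT",
  "TTGCAGATGAATAGCCTGAAACCGGAAGATACCGCGGTTTACTACTGTACCGTGACCGTGGGTAGCACGTACACGGGCCA",
  "AGGTACCCAAGTGACTGTGAGC"
)

# CDR primers that define each library's randomization scheme
.sybody_scheme_primers <- list(
  concave = c(CDR1 = "CDR1_a_b", CDR2 = "CDR2_a_b", CDR3 = "CDR3_a"),
  loop    = c(CDR1 = "CDR1_a_b", CDR2 = "CDR2_a_b", CDR3 = "CDR3_b"),
  convex  = c(CDR1 = "CDR1_c",   CDR2 = "CDR2_c",   CDR3 = "CDR3_c")
)

#' Built-in sybody library-assembly primers
#'
#' Returns the library-assembly primer sequences used to randomize and
#' assemble the three sybody libraries. Placeholder triplets \code{111},
#' \code{222} and \code{333} mark codon slots randomized with trinucleotide
#' mixes 1-3; all sequences are written 5' to 3'.
#'
#' @param name Optional primer name. When omitted, the full named vector is
#'   returned.
#' @return A named character vector of primer strings, or a single string.
#' @export
#' @examples
#' sybody_primer("CDR1_a_b")
sybody_primer <- function(name = NULL) {
  if (is.null(name)) return(.sybody_primers)
  if (!name %in% names(.sybody_primers)) {
    stop("unknown primer: ", name, call. = FALSE)
  }
  .sybody_primers[[name]]
}

#' Non-randomized sybody framework DNA
#'
#' The framework (scaffold) coding sequence of the non-randomized concave
#' sybody, i.e. the scaffold into which the randomized CDRs embed. The
#' scaffold carries serines/threonines at the positions that are randomized
#' in the library.
#'
#' @param library Library name; currently only \code{"concave"} has a
#'   built-in framework sequence.
#' @return A DNA string (plain character).
#' @export
sybody_framework <- function(library = "concave") {
  library <- match.arg(library, "concave")
  .sybody_framework_concave
}
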
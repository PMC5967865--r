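# Readers/writers for FASTA and the CSV schemas shared by the subcommands.

#' Write sequences to FASTA
#'
#' @param seqs A \code{DNAStringSet}/\code{AAStringSet} or named character
#'   vector.
#' @param path Output path.
#' @param width Line wrap width (default 60).
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  if (is.character(seqs)) seqs <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @param type \code{"DNA"}, \code{"AA"} or \code{"B"} (generic).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("DNA", "AA", "B")) {
  type <- match.arg(type)
  reader <- switch(type, DNA = Biostrings::readDNAStringSet,
                   AA = Biostrings::readAAStringSet,
                   B = Biostrings::readBStringSet)
  x <- reader(path)
  stats::setNames(as.character(x), names(x))
}

# read a CSV and fail with a schema error naming the file and columns
read_schema_csv <- function(path, required, optional = character(0)) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), " (expected ",
         paste(required, collapse = ", "), ")", call. = FALSE)
  }
  df
}

#' Read assay CSV files
#'
#' Schema-checked readers for the CSV formats used by the command-line
#' interface: sensorgrams (\code{time,response,concentration,phase}),
#' dose-response (\code{x,y}), melt curves (\code{temperature,signal}),
#' qPCR (\code{sample_id,Ct}) and ELISA plates (\code{signal,background}).
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_sensorgram_csv <- function(path) {
  read_schema_csv(path, c("time", "response", "concentration", "phase"))
}

#' @rdname read_sensorgram_csv
#' @export
read_dose_response_csv <- function(path) read_schema_csv(path, c("x", "y"))

#' @rdname read_sensorgram_csv
#' @export
read_melt_csv <- function(path) read_schema_csv(path, c("temperature", "signal"))

#' @rdname read_sensorgram_csv
#' @export
read_qpcr_csv <- function(path) read_schema_csv(path, c("sample_id", "Ct"))

#' @rdname read_sensorgram_csv
#' @export
read_elisa_csv <- function(path) read_schema_csv(path, c("signal", "background"))

#' Write a fit report as JSON
#'
#' @param fit A \code{fit_result}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  rep <- list(model = fit$model, converged = fit$converged,
              estimate = fit$estimate, se = fit$se,
              residual_norm = fit$residual_norm, message = fit$message)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
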
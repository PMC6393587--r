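#' Read and write FID records as plain CSV
#'
#' Dialect: two columns `time_us,amplitude`, preceded by header comment
#' lines `# temperature_K=...`, `# dead_time_us=...`, `# is_reference=0|1`.
#' Both LF and CRLF line endings are accepted.
#'
#' @param path file path.
#' @return [read_fid_csv()] returns a `fid_signal` (acquisition metadata is
#'   reconstructed from the header; generator-only fields take their
#'   defaults); [write_fid_csv()] returns `path` invisibly.
#' @export
read_fid_csv <- function(path) {
  lines <- sub("\r$", "", readLines(path))
  hdr <- grep("^#", lines, value = TRUE)
  get_key <- function(key) {
    m <- grep(paste0("^#\\s*", key, "\\s*="), hdr, value = TRUE)
    if (!length(m))
      stop("FID header is missing required key '", key, "' in ", path)
    as.numeric(sub(".*=\\s*", "", m[1]))
  }
  temperature <- get_key("temperature_K")
  dead_time <- get_key("dead_time_us")
  is_ref <- get_key("is_reference") == 1
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!identical(strsplit(body[1], ",")[[1]], c("time_us", "amplitude")))
    stop("expected a 'time_us,amplitude' column header in ", path)
  dat <- utils::read.csv(text = body, header = TRUE)
  if (any(diff(dat$time_us) <= 0))
    stop("non-monotone time column in ", path)
  dt <- if (nrow(dat) > 1) dat$time_us[2] - dat$time_us[1] else 1
  acq <- acquisition_params(dead_time = dead_time, sample_dt = dt,
                            t_max = max(dat$time_us, 1000))
  sig <- new_fid_signal(dat$time_us, dat$amplitude, temperature, is_ref, acq)
  sig
}

#' @rdname read_fid_csv
#' @param fid a `fid_signal`.
#' @export
write_fid_csv <- function(fid, path) {
  stopifnot(inherits(fid, "fid_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# temperature_K=%.10g", fid$temperature),
    sprintf("# dead_time_us=%.10g", fid$acquisition$dead_time),
    sprintf("# is_reference=%d", as.integer(fid$is_reference)),
    "time_us,amplitude"), con)
  writeLines(sprintf("%.10g,%.17g", fid$times, fid$amplitudes), con)
  invisible(path)
}

#' Read and write melting diagrams as TSV
#'
#' Columns: `T_C  T_K  T_fn  E_a_kJ_mol  n  n_se  h  dn_dTfn`.  Comment
#' lines starting with `#` carry provenance (package version, config hash)
#' and are ignored on read.
#'
#' @param diagram a `melting_diagram`.
#' @param path file path.
#' @param comments optional character vector written as `#` header lines.
#' @export
write_melting_tsv <- function(diagram, path, comments = character(0)) {
  stopifnot(inherits(diagram, "melting_diagram"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(format(as.data.frame(diagram), digits = 10, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_melting_tsv
#' @export
read_melting_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  need <- c("T_C", "T_K", "T_fn", "E_a_kJ_mol", "n", "n_se", "h", "dn_dTfn")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("melting TSV is missing column(s): ", paste(miss, collapse = ", "))
  df <- df[order(df$T_C), need]
  rownames(df) <- NULL
  class(df) <- c("melting_diagram", "data.frame")
  df
}
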
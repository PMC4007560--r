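#' Write the per-probe scaling / QC table
#'
#' One CSV row per scored probe: QC columns (`r`, `p`, `q`, `pass`,
#' `n_train`) merged with scaling parameters (`m`, `b` and the four anchor
#' quantiles). Probes that failed QC (or were unscalable) appear with
#' `pass = FALSE` and empty `m`/`b`. Floats are written with 15 significant
#' digits so a read-back reproduces them to at least 12.
#'
#' @param qc data.frame of probe QC records (from [assign_pass()] /
#'   [probe_qc()]), columns `probe_id`, `gene_id`, `r`, `p`, `q`, `pass`,
#'   `n_train`.
#' @param params data.frame of scaling parameters (from [fit_scaling()]);
#'   may cover only a subset of probes. `NULL` writes QC columns alone.
#' @param path output CSV path.
#' @param comments character vector of `# `-prefixed header comment lines.
#' @return `path`, invisibly.
#' @export
write_scaling_table <- function(qc, params = NULL, path, comments = character()) {
  cols <- c("probe_id", "gene_id", "m", "b", "r", "p", "q", "pass",
            "q05_array", "q95_array", "q05_seq", "q95_seq", "n_train")
  nr <- nrow(qc)
  out <- data.frame(probe_id = qc$probe_id, gene_id = qc$gene_id,
                    m = rep(NA_real_, nr), b = rep(NA_real_, nr),
                    r = qc$r, p = qc$p, q = qc$q, pass = qc$pass,
                    q05_array = rep(NA_real_, nr), q95_array = rep(NA_real_, nr),
                    q05_seq = rep(NA_real_, nr), q95_seq = rep(NA_real_, nr),
                    n_train = qc$n_train,
                    stringsAsFactors = FALSE)
  if (!is.null(params) && nrow(params) > 0) {
    idx <- match(params$probe_id, out$probe_id)
    for (cn in c("m", "b", "q05_array", "q95_array", "q05_seq", "q95_seq"))
      out[[cn]][idx] <- params[[cn]]
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con)
  writeLines(paste(cols, collapse = ","), con)
  if (nrow(out) > 0) {
    fmt <- function(x) ifelse(is.na(x), "", sprintf("%.15g", x))
    lines <- paste(out$probe_id, out$gene_id,
                   fmt(out$m), fmt(out$b), fmt(out$r), fmt(out$p), fmt(out$q),
                   ifelse(is.na(out$pass), "", ifelse(out$pass, "true", "false")),
                   fmt(out$q05_array), fmt(out$q95_array),
                   fmt(out$q05_seq), fmt(out$q95_seq),
                   ifelse(is.na(out$n_train), "", as.character(out$n_train)),
                   sep = ",")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read back a scaling / QC table written by [write_scaling_table()]
#' @param path CSV path.
#' @return data.frame with the table's 13 columns; empty cells become `NA`.
#' @export
read_scaling_table <- function(path) {
  if (!file.exists(path))
    stop("scaling table not found: ", path)
  df <- utils::read.csv(path, header = TRUE, comment.char = "#",
                        stringsAsFactors = FALSE,
                        colClasses = c(probe_id = "character",
                                       gene_id = "character",
                                       pass = "character"))
  num <- c("m", "b", "r", "p", "q", "q05_array", "q95_array",
           "q05_seq", "q95_seq", "n_train")
  for (cn in num) df[[cn]] <- as.numeric(df[[cn]])
  df$pass <- ifelse(df$pass == "", NA, df$pass == "true")
  df
}
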
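#' Collect per-sample beta vectors into a beta matrix data frame
#'
#' @param vectors List of `beta_vector` objects from [quantify_sample()].
#' @return Data frame: `sample_id`, one column per probe, `conversion_rate`,
#'   `total_depth`.
#' @export
beta_matrix_from_vectors <- function(vectors) {
  do.call(rbind, lapply(vectors, function(v) {
    cbind(data.frame(sample_id = v$sample_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(v$beta)),
          data.frame(conversion_rate = v$conversion_rate,
                     total_depth = sum(v$per_probe_depth, na.rm = TRUE)))
  }))
}

#' Read / write a beta matrix as tab-separated text
#'
#' The on-disk format is one row per sample: `sample_id`, probe columns,
#' and any extra columns (`conversion_rate`, depth, `patient_id`).
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_beta_matrix <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_beta_matrix
#' @param beta_matrix Data frame to write.
#' @export
write_beta_matrix <- function(beta_matrix, path) {
  utils::write.table(beta_matrix, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a clinical table from CSV
#'
#' Column names can be remapped via `mapping`, e.g.
#' `c(time = "os_months", event = "os_event")`. Expected logical columns:
#' `sample_id`, `patient_id`, `time`, `event`, `response`, optionally
#' `endpoint_kind` and `timepoint`.
#'
#' @param path CSV path.
#' @param mapping Named character vector: names are canonical column names,
#'   values the columns in the file.
#' @return Data frame with canonical column names; `time` and `event`
#'   validated (`time > 0`, `event` in 0/1).
#' @export
read_clinical <- function(path, mapping = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    for (canon in names(mapping)) {
      src <- mapping[[canon]]
      if (!src %in% names(d)) stop("clinical file lacks column: ", src)
      names(d)[names(d) == src] <- canon
    }
  }
  if ("time" %in% names(d) && any(d$time <= 0, na.rm = TRUE)) {
    stop("survival times must be positive")
  }
  if ("event" %in% names(d) && !all(d$event %in% c(0, 1, NA))) {
    stop("event indicator must be 0/1")
  }
  d
}

#' Extract the probe columns of a beta matrix as a numeric matrix
#'
#' @param beta_matrix Data frame as read by [read_beta_matrix()].
#' @param probes Probe column names; default: columns matching `^P\\d+$`.
#' @return Numeric matrix, samples x probes, rownames from `sample_id`.
#' @export
probe_columns <- function(beta_matrix, probes = NULL) {
  if (is.null(probes)) probes <- grep("^P\\d+$", names(beta_matrix), value = TRUE)
  m <- as.matrix(beta_matrix[, probes, drop = FALSE])
  if ("sample_id" %in% names(beta_matrix)) rownames(m) <- beta_matrix$sample_id
  m
}
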
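# Plain-text and RDS serialization for the pipeline's tables and epoch
# containers, with schema checks on read.

#' Write/read a cohort behavior table as CSV
#'
#' Columns: subject_id, group, block, block_order, trial, choice, outcome,
#' is_win, cumulative (plus any extras, preserved).
#'
#' @param behavior Long behavior table.
#' @param path File path.
#' @return `write_behavior_csv` returns the path invisibly;
#'   `read_behavior_csv` returns the table.
#' @export
write_behavior_csv <- function(behavior, path) {
  utils::write.csv(behavior, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior_csv
#' @export
read_behavior_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "block", "trial", "choice", "outcome")
  miss <- setdiff(req, names(out))
  if (length(miss)) {
    stop("behavior CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(!out$choice %in% c("RareG", "RareL"))
  if (length(bad)) {
    stop("invalid choice value at row ", bad[1], ": '", out$choice[bad[1]], "'")
  }
  out
}

#' Write/read a covariate table as CSV
#' @param covariates Covariate table.
#' @param path File path.
#' @return Path (write) or table (read).
#' @export
write_covariates_csv <- function(covariates, path) {
  utils::write.csv(covariates, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_covariates_csv
#' @export
read_covariates_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "group")
  miss <- setdiff(req, names(out))
  if (length(miss)) {
    stop("covariate CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  out
}

#' Write/read an epoch set
#'
#' Epoch arrays are stored as a versioned RDS payload (exact binary
#' round-trip of the trials x channels x samples array plus metadata).
#'
#' @param epochs An `epoch_set`.
#' @param path File path (conventionally `.rds`).
#' @return Path (write) or `epoch_set` (read).
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  saveRDS(list(format = "luckydoor-epochs", version = 1L,
               payload = unclass(epochs)), path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "luckydoor-epochs")) {
    stop("not a luckydoor epochs file: ", path)
  }
  p <- obj$payload
  epoch_set(p$subject_id, p$data, p$srate, p$window, p$channels,
            p$trial_info)
}

#' Round-trip a pipeline object through its on-disk format
#'
#' Writes `object` to `path` in the named format and reads it back,
#' returning the parsed object. Used to validate that serialization is
#' lossless.
#'
#' @param object The in-memory object.
#' @param path Destination file.
#' @param kind One of `"events_csv"` (behavior table), `"covariates_csv"`,
#'   `"epochs_rds"`.
#' @return The re-parsed object.
#' @export
read_write_roundtrip <- function(object, path,
                                 kind = c("events_csv", "covariates_csv",
                                          "epochs_rds")) {
  kind <- match.arg(kind)
  switch(kind,
    events_csv = { write_behavior_csv(object, path); read_behavior_csv(path) },
    covariates_csv = { write_covariates_csv(object, path)
                       read_covariates_csv(path) },
    epochs_rds = { write_epochs(object, path); read_epochs(path) }
  )
}

#' Flatten per-subject band scalars to a tidy table
#'
#' @param scalars Named list (by subject) of named lists (by band) of
#'   channels x periods matrices.
#' @return Tidy `data.frame`: `subject_id`, `band`, `channel`, `period`,
#'   `value`.
#' @export
scalars_to_tidy <- function(scalars) {
  rows <- list()
  for (id in names(scalars)) {
    for (bn in names(scalars[[id]])) {
      m <- scalars[[id]][[bn]]
      rows[[paste(id, bn)]] <- data.frame(
        subject_id = id, band = bn,
        channel = rep(rownames(m), times = ncol(m)),
        period = rep(colnames(m), each = nrow(m)),
        value = as.vector(m), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
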
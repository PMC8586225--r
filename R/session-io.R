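SESSION_COLUMNS <- c("time_s", "wr_w", "hr_bpm", "hrr_frac", "bf_brpm",
                     "ve_lmin", "vo2_mlmin")

#' Read and write exercise sessions as delimited text
#'
#' Sessions are stored as CSV with a header row and the canonical columns
#' \code{time_s, wr_w, hr_bpm, hrr_frac, bf_brpm, ve_lmin, vo2_mlmin} plus
#' an optional \code{vo2_truth_mlmin} latent-truth column for synthetic
#' data.  Session metadata (participant id, protocol label, mass, HR
#' limits) travels in \code{#}-prefixed header comments so the file remains
#' plain CSV.  Round-trips are lossless to numeric precision.
#'
#' @param session a \code{vo2_session} data.frame.
#' @param path file path.
#' @return \code{read_session}: a \code{vo2_session};
#'   \code{write_session}: the path, invisibly.
#' @export
write_session <- function(session, path) {
  proto <- attr(session, "protocol")
  meta <- c(participant_id = attr(session, "participant_id") %||% "",
            mass = attr(session, "mass") %||% "",
            hr_rest = attr(session, "hr_rest") %||% "",
            hr_max = attr(session, "hr_max") %||% "")
  if (!is.null(proto)) {
    pv <- vapply(proto, function(v) as.character(v)[1], "")
    names(pv) <- paste0("protocol.", names(proto))
    meta <- c(meta, pv)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), meta), con)
  utils::write.csv(as.data.frame(session), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  missing <- setdiff(SESSION_COLUMNS, names(df))
  if (length(missing))
    stop("session file lacks required column(s): ",
         paste(missing, collapse = ", "))
  for (col in intersect(c(SESSION_COLUMNS, "vo2_truth_mlmin"), names(df)))
    if (anyNA(df[[col]]) || any(!is.finite(df[[col]])))
      stop("non-finite values in column '", col, "'")
  if (any(diff(df$time_s) <= 0))
    stop("time_s must be strictly increasing")
  if (any(df$vo2_mlmin <= 0)) stop("vo2_mlmin must be positive")
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- trimws(sub("^[^:]*:\\s*", "", kv))
  }
  attr(df, "participant_id") <- meta$participant_id %||% NA_character_
  pf <- meta[grep("^protocol\\.", names(meta))]
  if (length(pf)) {
    names(pf) <- sub("^protocol\\.", "", names(pf))
    proto <- lapply(pf, function(v) {
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num)) v else num
    })
    if (!is.null(proto$n_repetitions))
      proto$n_repetitions <- as.integer(proto$n_repetitions)
    class(proto) <- "protocol_spec"
    attr(df, "protocol") <- proto
  }
  for (f in c("mass", "hr_rest", "hr_max"))
    if (!is.null(meta[[f]]) && nzchar(meta[[f]]))
      attr(df, f) <- as.numeric(meta[[f]])
  class(df) <- c("vo2_session", "data.frame")
  df
}

#' Write or read a cohort directory
#'
#' One CSV per session plus a \code{manifest.csv} listing participant id,
#' protocol label, and file name.
#'
#' @param cohort a \code{vo2_cohort} (or session list).
#' @param dir output directory (created if needed).
#' @return \code{write_cohort}: the manifest data.frame, invisibly;
#'   \code{read_cohort}: a list of sessions.
#' @export
write_cohort <- function(cohort, dir) {
  sessions <- if (inherits(cohort, "vo2_cohort")) cohort$sessions else cohort
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    fn <- sprintf("%s_%s.csv", attr(s, "participant_id") %||% sprintf("S%02d", i),
                  gsub("[^A-Za-z0-9]", "", attr(s, "protocol")$label %||% "session"))
    write_session(s, file.path(dir, fn))
    data.frame(participant_id = attr(s, "participant_id") %||% "",
               protocol = attr(s, "protocol")$label %||% "", file = fn)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  mf <- utils::read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(mf)), function(i) read_session(file.path(dir, mf$file[i])))
}
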
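# Delimited-table I/O for comparison records and the key = value scenario
# config format consumed by the command-line wrapper.

RECORD_COLUMNS <- c("sample_id", "sex", "condition", "expected", "detected",
                    "drop_in", "drop_out", "recovery_pct")

#' Write comparison records as a delimited table
#'
#' @param records Comparison-record data frame.
#' @param path Output path (CSV).
#' @return Invisibly, \code{path}.
#' @export
write_records <- function(records, path) {
  stopifnot(all(RECORD_COLUMNS %in% names(records)))
  utils::write.csv(records[, RECORD_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read comparison records written by \code{\link{write_records}}
#'
#' Counts are re-validated and the derived columns recomputed, so a table
#' edited by hand cannot smuggle in an inconsistent drop-out count or
#' recovery percentage.
#'
#' @param path Input path.
#' @return Comparison-record data frame.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "expected", "detected")
  if (!all(need %in% names(tab)))
    stop("record table needs columns: ", paste(need, collapse = ", "))
  if (!nrow(tab)) stop("record table is empty")
  comparison_records(
    sample_id = tab$sample_id,
    sex = if (is.null(tab$sex)) unname(vapply(tab$sample_id, infer_sex, ""))
          else tab$sex,
    condition = if (is.null(tab$condition)) NA else tab$condition,
    expected = tab$expected, detected = tab$detected,
    drop_in = if (is.null(tab$drop_in)) 0L else tab$drop_in
  )
}

#' Read a simulation scenario config
#'
#' Plain-text \code{key = value} format (\code{#} comments allowed), with
#' keys for either condition prefixed \code{pre.} / \code{post.}:
#' \code{p_detect}, \code{dropin_rate}, \code{height_mean},
#' \code{height_cv}, plus global \code{n_subjects} and
#' \code{shedder_multipliers} as \code{high,intermediate,low}.
#'
#' @param path Config file path.
#' @return List: \code{n_subjects}, \code{params_pre}, \code{params_post}.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2L)
  if (length(bad)) stop("malformed config line: ", lines[bad[[1]]])
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  opt <- stats::setNames(as.list(vals), keys)

  num <- function(key, default) {
    if (is.null(opt[[key]])) return(default)
    v <- suppressWarnings(as.numeric(opt[[key]]))
    if (is.na(v)) stop("non-numeric value for ", key)
    v
  }
  mult <- c(high = 1.15, intermediate = 1, low = 0.6)
  if (!is.null(opt$shedder_multipliers)) {
    v <- as.numeric(strsplit(opt$shedder_multipliers, ",")[[1]])
    if (length(v) != 3L || anyNA(v))
      stop("shedder_multipliers must be three numbers: high,intermediate,low")
    mult <- stats::setNames(v, c("high", "intermediate", "low"))
  }
  cond <- function(prefix, base) {
    sim_params(
      p_detect = num(paste0(prefix, ".p_detect"), base$p_detect),
      dropin_rate = num(paste0(prefix, ".dropin_rate"), base$dropin_rate),
      shedder_multipliers = mult,
      height_mean = num(paste0(prefix, ".height_mean"), base$height_mean),
      height_cv = num(paste0(prefix, ".height_cv"), base$height_cv)
    )
  }
  list(n_subjects = as.integer(num("n_subjects", 12)),
       params_pre = cond("pre", sim_params_prewash()),
       params_post = cond("post", sim_params_postwash()))
}
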
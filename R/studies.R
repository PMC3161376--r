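#' Assemble a validated table of studies
#'
#' A study carries either the four cells of a 2x2 arm-count table
#' (`events_trt`, `n_trt`, `events_ctl`, `n_ctl`) or a precomputed effect on
#' the log odds ratio scale (`y`, `se`) — never both: supplying both for the
#' same study is rejected rather than silently prioritized, so the two input
#' modes cannot disagree unnoticed.
#'
#' @param id character vector of short unique study identifiers.
#' @param label display labels; defaults to `id`.
#' @param events_trt,n_trt,events_ctl,n_ctl non-negative integer arm counts
#'   (all four present, or all `NA` for effect-mode studies).
#' @param y,se log odds ratio and its standard error (`se > 0`), or `NA` for
#'   count-mode studies.
#' @param included logical inclusion flag, default `TRUE`.
#' @return A `data.frame` of class `ht_studies` with one row per study.
#' @seealso [read_studies()], [compute_log_or()], [run_meta()]
#' @export
studies <- function(id, label = id,
                    events_trt = NA, n_trt = NA,
                    events_ctl = NA, n_ctl = NA,
                    y = NA, se = NA, included = TRUE) {
  df <- data.frame(
    id = as.character(id), label = as.character(label),
    events_trt = as.numeric(events_trt), n_trt = as.numeric(n_trt),
    events_ctl = as.numeric(events_ctl), n_ctl = as.numeric(n_ctl),
    y = as.numeric(y), se = as.numeric(se),
    included = as.logical(included),
    stringsAsFactors = FALSE
  )
  validate_studies(df)
}

validate_studies <- function(df) {
  if (anyDuplicated(df$id)) abort("study ids must be unique")
  counts <- !is.na(df$events_trt) | !is.na(df$n_trt) |
    !is.na(df$events_ctl) | !is.na(df$n_ctl)
  counts_full <- !is.na(df$events_trt) & !is.na(df$n_trt) &
    !is.na(df$events_ctl) & !is.na(df$n_ctl)
  effect <- !is.na(df$y) | !is.na(df$se)
  effect_full <- !is.na(df$y) & !is.na(df$se)
  for (i in seq_len(nrow(df))) {
    if (counts[i] && effect[i])
      abort("study '", df$id[i], "': supply counts or (y, se), not both")
    if (!counts[i] && !effect[i])
      abort("study '", df$id[i], "': supply counts or (y, se)")
    if (counts[i]) {
      if (!counts_full[i])
        abort("study '", df$id[i], "': incomplete 2x2 counts")
      cells <- unlist(df[i, c("events_trt", "n_trt", "events_ctl", "n_ctl")])
      if (any(cells < 0) || any(cells != round(cells)))
        abort("study '", df$id[i], "': counts must be non-negative integers")
      if (df$events_trt[i] > df$n_trt[i] || df$events_ctl[i] > df$n_ctl[i])
        abort("study '", df$id[i], "': events exceed arm size")
    } else {
      if (!effect_full[i])
        abort("study '", df$id[i], "': incomplete (y, se) pair")
      if (df$se[i] <= 0)
        abort("study '", df$id[i], "': se must be > 0")
    }
  }
  class(df) <- c("ht_studies", "data.frame")
  df
}

#' Read or write a study table as CSV
#'
#' The CSV dialect is UTF-8, comma-separated with `.` as decimal mark and the
#' header `id,label,events_trt,n_trt,events_ctl,n_ctl,y,se,included`; fields
#' of the unused input mode are left empty.
#'
#' @param path file path.
#' @param x a `ht_studies` table (for writing).
#' @return `read_studies()` returns a validated `ht_studies` table;
#'   `write_studies()` returns `path` invisibly.
#' @export
read_studies <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "label", "events_trt", "n_trt", "events_ctl", "n_ctl",
            "y", "se", "included")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort("studies file missing columns: ",
                          paste(miss, collapse = ", "))
  studies(df$id, df$label, df$events_trt, df$n_trt, df$events_ctl, df$n_ctl,
          df$y, df$se, df$included)
}

#' @rdname read_studies
#' @export
write_studies <- function(x, path) {
  stopifnot(inherits(x, "ht_studies"))
  write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Log odds ratio and standard error from a 2x2 table
#'
#' Computes `y = log[(a d)/(b c)]` and `se = sqrt(1/a + 1/b + 1/c + 1/d)`
#' from the cells a = treated events, b = treated non-events, c = control
#' events, d = control non-events.  When any cell is zero the
#' Haldane-Anscombe continuity correction adds `continuity` to all four
#' cells; tables without zeros are left untouched.
#'
#' @param events_trt,n_trt,events_ctl,n_ctl the 2x2 arm counts.
#' @param continuity non-negative correction added to every cell when any
#'   cell is zero (default 0.5).
#' @return list with elements `y` and `se`.
#' @examples
#' compute_log_or(5, 50, 10, 50)  # log(4/9)
#' @export
compute_log_or <- function(events_trt, n_trt, events_ctl, n_ctl,
                           continuity = 0.5) {
  stopifnot(is_scalar_num(continuity), continuity >= 0)
  a <- events_trt; b <- n_trt - events_trt
  c <- events_ctl; d <- n_ctl - events_ctl
  if (n_trt <= 0 || n_ctl <= 0)
    abort("degenerate arm: no events and no non-events (arm size 0)")
  if (min(a, b, c, d) < 0) abort("events exceed arm size")
  if (any(c(a, b, c, d) == 0)) {
    if ((a == 0 && b == 0) || (c == 0 && d == 0))
      abort("degenerate arm: no events and no non-events")
    a <- a + continuity; b <- b + continuity
    c <- c + continuity; d <- d + continuity
    if (continuity == 0)
      abort("zero cell with continuity = 0: log odds ratio undefined")
  }
  list(y = log((a * d) / (b * c)),
       se = sqrt(1 / a + 1 / b + 1 / c + 1 / d))
}

# y/se for every included study: counts are converted, effect-mode studies
# pass through unchanged
study_effects <- function(st, continuity = 0.5) {
  eff <- lapply(seq_len(nrow(st)), function(i) {
    if (!is.na(st$y[i])) return(list(y = st$y[i], se = st$se[i]))
    compute_log_or(st$events_trt[i], st$n_trt[i],
                   st$events_ctl[i], st$n_ctl[i], continuity)
  })
  data.frame(
    study_id = st$id, label = st$label,
    y = vapply(eff, `[[`, numeric(1), "y"),
    se = vapply(eff, `[[`, numeric(1), "se"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.ht_studies <- function(x, ...) {
  cat("<ht_studies> ", nrow(x), " studies (",
      sum(x$included), " included)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
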
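#' Sample validation windows per bird
#'
#' Draws `n_per_bird` feature windows per listed bird without replacement
#' (reproducibly for a fixed seed), then removes windows flagged as
#' colony-period and reports how many were excluded — mirroring a
#' validation design of 50 windows per bird with at-colony observations
#' dropped afterwards.
#'
#' @param features feature tibble with `individual_id` and `window_index`.
#' @param birds bird ids to sample from (default: all).
#' @param n_per_bird windows per bird (default 50).
#' @param colony_mask optional logical vector along `features` rows marking
#'   at-colony windows, excluded after sampling.
#' @param seed integer seed.
#' @return The sampled subset (tibble) with attribute `n_colony_excluded`.
#' @export
sample_validation_windows <- function(features, birds = NULL,
                                      n_per_bird = 50, colony_mask = NULL,
                                      seed = 1) {
  birds <- birds %||% unique(features$individual_id)
  if (!is.null(colony_mask)) {
    stopifnot(length(colony_mask) == nrow(features))
    features$.colony <- colony_mask
  } else {
    features$.colony <- FALSE
  }
  set.seed(seed)
  picked <- lapply(birds, function(b) {
    rows <- which(features$individual_id == b)
    if (length(rows) < n_per_bird) {
      stop("bird ", b, " has only ", length(rows), " windows (need ",
           n_per_bird, ")", call. = FALSE)
    }
    sort(sample(rows, n_per_bird))
  })
  out <- features[unlist(picked), , drop = FALSE]
  n_col <- sum(out$.colony)
  out <- out[!out$.colony, , drop = FALSE]
  out$.colony <- NULL
  attr(out, "n_colony_excluded") <- n_col
  out
}

#' Confusion matrix with exact binomial accuracy interval
#'
#' Cross-tabulates assigned against true labels (rows = model-assigned,
#' columns = true), computes per-true-class column percentages, overall
#' accuracy (the percentage of observations whose assigned state matches
#' the true state), and an exact Clopper-Pearson 95% interval on accuracy.
#'
#' @param true_labels,assigned_labels equal-length label vectors.
#' @param levels the state alphabet (default: union of observed labels).
#' @return Object of class `soarhmm_confusion`: `counts`, `col_pct`,
#'   `accuracy` (%), `ci` (%, length 2), `n`.
#' @examples
#' cm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
#' cm$accuracy
#' @export
confusion_matrix <- function(true_labels, assigned_labels, levels = NULL) {
  stopifnot(length(true_labels) == length(assigned_labels))
  levels <- levels %||% sort(unique(c(true_labels, assigned_labels)))
  bad <- setdiff(unique(c(true_labels, assigned_labels)), levels)
  if (length(bad)) stop("label outside alphabet: ", bad[1], call. = FALSE)
  counts <- table(
    assigned = factor(assigned_labels, levels = levels),
    true = factor(true_labels, levels = levels)
  )
  counts <- unclass(counts)
  col_pct <- sweep(counts, 2, pmax(colSums(counts), 1), "/") * 100
  n <- sum(counts)
  correct <- sum(diag(counts))
  ci <- as.numeric(binom.test(correct, n)$conf.int) * 100
  structure(
    list(counts = counts, col_pct = col_pct,
         accuracy = 100 * correct / n, ci = ci, n = n),
    class = "soarhmm_confusion"
  )
}

#' @export
print.soarhmm_confusion <- function(x, ...) {
  cat("<confusion matrix: rows = assigned, cols = true; column %>\n")
  print(round(x$col_pct, 1))
  cat(sprintf("Overall accuracy: %.1f%% (%.1f, %.1f), n = %d\n",
              x$accuracy, x$ci[1], x$ci[2], x$n))
  invisible(x)
}

#' Per-group confusion matrices plus the pooled matrix
#'
#' One confusion matrix per group (e.g. species) and the pooled matrix;
#' pooled counts equal the element-wise sum of group counts. Empty groups
#' are reported, not silently dropped.
#'
#' @param data tibble holding label and group columns.
#' @param true,assigned,group column names.
#' @param levels state alphabet passed to [confusion_matrix()].
#' @return List with `groups` (named list of `soarhmm_confusion`), `pooled`,
#'   and `empty_groups`.
#' @export
grouped_accuracy <- function(data, true = "true_state", assigned = "state",
                             group = "covariate", levels = NULL) {
  stopifnot(all(c(true, assigned, group) %in% names(data)))
  levels <- levels %||% sort(unique(c(data[[true]], data[[assigned]])))
  gl <- unique(data[[group]])
  out <- list()
  empty <- character()
  for (g in gl) {
    rows <- data[[group]] == g
    if (!any(rows)) { empty <- c(empty, g); next }
    out[[as.character(g)]] <- confusion_matrix(
      data[[true]][rows], data[[assigned]][rows], levels
    )
  }
  list(groups = out,
       pooled = confusion_matrix(data[[true]], data[[assigned]], levels),
       empty_groups = empty)
}

#' Extract behavioral bouts from a decoded state sequence
#'
#' A bout is a maximal run of consecutive windows in the same state;
#' concatenating bouts reconstructs the sequence. Durations are in minutes
#' (`windows x window_s / 60`).
#'
#' @param states state label vector in time order, or a decode tibble with
#'   `individual_id` and `state` (then bouts are extracted per individual).
#' @param window_s window length in seconds (default 30).
#' @return Tibble: `individual_id`, `state`, `start_window`, `end_window`,
#'   `n_windows`, `duration_min`.
#' @examples
#' extract_bouts(c("A", "A", "A", "B", "B", "A"))
#' @export
extract_bouts <- function(states, window_s = 30) {
  if (is.data.frame(states)) {
    return(dplyr::bind_rows(lapply(
      split(states, states$individual_id), function(d) {
        b <- extract_bouts(d$state[order(d$window_index)], window_s)
        b$individual_id <- d$individual_id[1]
        dplyr::relocate(b, "individual_id")
      }
    )))
  }
  r <- rle(as.character(states))
  ends <- cumsum(r$lengths)
  tibble::tibble(
    state = r$values,
    start_window = ends - r$lengths + 1L,
    end_window = ends,
    n_windows = r$lengths,
    duration_min = r$lengths * window_s / 60
  )
}

#' Time-activity budget
#'
#' Percentage of (at-sea) windows spent in each state, per individual;
#' percentages sum to 100.
#'
#' @param states decode tibble with `individual_id`, `window_index`,
#'   `state`, or a plain label vector.
#' @param at_sea_mask optional logical mask along the rows restricting the
#'   budget to at-sea windows.
#' @param levels state alphabet (default: observed states).
#' @return Tibble: `individual_id`, `state`, `n_windows`, `pct`.
#' @export
activity_budget <- function(states, at_sea_mask = NULL, levels = NULL) {
  if (!is.data.frame(states)) {
    states <- tibble::tibble(individual_id = "ind1",
                             window_index = seq_along(states),
                             state = as.character(states))
  }
  if (!is.null(at_sea_mask)) {
    stopifnot(length(at_sea_mask) == nrow(states))
    states <- states[at_sea_mask, , drop = FALSE]
  }
  if (nrow(states) == 0) stop("empty at-sea mask", call. = FALSE)
  levels <- levels %||% sort(unique(states$state))
  states |>
    dplyr::filter(!is.na(.data$state)) |>
    dplyr::count(.data$individual_id,
                 state = factor(.data$state, levels = levels),
                 .drop = FALSE, name = "n_windows") |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::mutate(pct = 100 * .data$n_windows / sum(.data$n_windows)) |>
    dplyr::ungroup() |>
    dplyr::mutate(state = as.character(.data$state))
}
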
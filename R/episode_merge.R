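## Merge HIP and PPS episodes into final episodes with support flags and
## outcome concordance scores.

#' Pair and merge overlapping HIP and PPS episodes
#'
#' Builds the bipartite overlap graph between the two episode sets (closed
#' intervals, overlap of at least one day) and resolves it greedily in
#' ascending distance between episode end dates (ties: earlier start, then
#' input order), so an episode overlapping several on the other side keeps
#' the pairing with the closest end date. Each surviving pair merges to the
#' union `[min(starts), max(ends)]` with both support flags set; unpaired
#' episodes pass through with a single flag. A final deterministic clip
#' enforces non-overlap of the merged set.
#'
#' @param hip_eps HIP episodes from [hip_episodes()].
#' @param pps_eps PPS episodes from [pps_episodes()].
#' @return `data.table(person_id, start_date, end_date, hip_flag, pps_flag,
#'   hip_outcome_category, hip_outcome_date, pps_outcome_category,
#'   pps_outcome_date, max_week, recorded_start_date)`.
#' @export
resolve_overlaps <- function(hip_eps, pps_eps) {
  h <- as.data.table(hip_eps)
  p <- as.data.table(pps_eps)
  rows <- vector("list", 0)
  emit <- function(pid, s, e, hf, pf, hc, hd, pc, pd, mw, rs) {
    rows[[length(rows) + 1L]] <<- data.table(
      person_id = pid, start_date = s, end_date = e,
      hip_flag = hf, pps_flag = pf,
      hip_outcome_category = hc, hip_outcome_date = hd,
      pps_outcome_category = pc, pps_outcome_date = pd,
      max_week = mw, recorded_start_date = rs)
  }
  pids <- unique(c(h$person_id, p$person_id))
  for (pid in pids) {
    hs <- h[person_id == pid]
    ps <- p[person_id == pid]
    p_start <- ps$first_event_date
    p_end <- ps$end_date
    ## candidate pairs with |end - end| weight
    pairs <- NULL
    if (nrow(hs) && nrow(ps)) {
      grid <- expand.grid(i = seq_len(nrow(hs)), j = seq_len(nrow(ps)))
      ov <- hs$start_date[grid$i] <= p_end[grid$j] &
        p_start[grid$j] <= hs$end_date[grid$i]
      grid <- grid[ov, , drop = FALSE]
      if (nrow(grid)) {
        grid$w <- abs(as.numeric(hs$end_date[grid$i]) - as.numeric(p_end[grid$j]))
        grid$s <- pmin(as.numeric(hs$start_date[grid$i]), as.numeric(p_start[grid$j]))
        pairs <- grid[order(grid$w, grid$s, grid$i, grid$j), , drop = FALSE]
      }
    }
    h_used <- rep(FALSE, nrow(hs)); p_used <- rep(FALSE, nrow(ps))
    if (!is.null(pairs)) {
      for (r in seq_len(nrow(pairs))) {
        i <- pairs$i[r]; j <- pairs$j[r]
        if (h_used[i] || p_used[j]) next
        h_used[i] <- TRUE; p_used[j] <- TRUE
        emit(pid,
             min(hs$start_date[i], p_start[j]),
             max(hs$end_date[i], p_end[j]),
             TRUE, TRUE,
             hs$outcome_category[i], hs$outcome_date[i],
             ps$outcome_category[j], ps$outcome_date[j],
             hs$max_week[i],
             min(hs$recorded_start_date[i], p_start[j]))
      }
    }
    for (i in which(!h_used)) {
      emit(pid, hs$start_date[i], hs$end_date[i], TRUE, FALSE,
           hs$outcome_category[i], hs$outcome_date[i],
           "NONE", as.Date(NA), hs$max_week[i], hs$recorded_start_date[i])
    }
    for (j in which(!p_used)) {
      emit(pid, p_start[j], p_end[j], FALSE, TRUE,
           "NONE", as.Date(NA),
           ps$outcome_category[j], ps$outcome_date[j],
           NA_integer_, p_start[j])
    }
  }
  res <- if (length(rows)) rbindlist(rows) else
    data.table(person_id = character(), start_date = as.Date(character()),
               end_date = as.Date(character()), hip_flag = logical(),
               pps_flag = logical(), hip_outcome_category = character(),
               hip_outcome_date = as.Date(character()),
               pps_outcome_category = character(),
               pps_outcome_date = as.Date(character()),
               max_week = integer(), recorded_start_date = as.Date(character()))
  .clip_overlaps(res)
}

#' Final outcome and concordance score for one episode
#'
#' Score 2: categories match, outcome dates within 14 days, and the
#' estimated gestational age at the outcome lies within the category's
#' expected term-duration window. Score 1: gestational age in-window but no
#' cross-algorithm outcome match (including the single-algorithm case).
#' Score 0: gestational age outside the window, even with an outcome match.
#' On category mismatch (or matching categories dated more than 14 days
#' apart) the later-dated outcome is kept as final; when only one algorithm
#' has an outcome it is adopted.
#'
#' @param hip_outcome list `(category, date)` or NULL.
#' @param pps_outcome list `(category, date)` or NULL.
#' @param inferred_ga_at_outcome_days estimated gestational age in days at
#'   the final outcome date, or NA when no start could be inferred.
#' @param config a [hierarchy_config()].
#' @return list `(outcome_category, outcome_date, score)`; score NA when
#'   neither algorithm has an outcome.
#' @export
concordance <- function(hip_outcome, pps_outcome,
                        inferred_ga_at_outcome_days = NA,
                        config = hierarchy_config()) {
  norm <- function(o) {
    if (is.null(o) || is.null(o$category) || is.na(o$category) ||
        o$category == "NONE") NULL else o
  }
  ho <- norm(hip_outcome); po <- norm(pps_outcome)
  if (is.null(ho) && is.null(po)) {
    return(list(outcome_category = "NONE", outcome_date = as.Date(NA),
                score = NA_integer_))
  }
  ga_in_window <- function(cat) {
    !is.na(inferred_ga_at_outcome_days) && {
      tw <- term_window(config, cat)
      inferred_ga_at_outcome_days >= tw[1] && inferred_ga_at_outcome_days <= tw[2]
    }
  }
  if (is.null(ho) || is.null(po)) {
    o <- if (is.null(ho)) po else ho
    return(list(outcome_category = o$category, outcome_date = .as_date(o$date),
                score = if (ga_in_window(o$category)) 1L else 0L))
  }
  matched <- ho$category == po$category &&
    abs(.days(.as_date(ho$date), .as_date(po$date))) <= 14
  if (matched) {
    final_date <- max(.as_date(ho$date), .as_date(po$date))
    return(list(outcome_category = ho$category, outcome_date = final_date,
                score = if (ga_in_window(ho$category)) 2L else 0L))
  }
  ## mismatch (or same category too far apart): keep the later outcome
  later <- if (.as_date(po$date) > .as_date(ho$date)) po else ho
  list(outcome_category = later$category, outcome_date = .as_date(later$date),
       score = if (ga_in_window(later$category)) 1L else 0L)
}
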
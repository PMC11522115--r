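# Shared fixtures: hand-built traces, a transcription of the published
# bedside decision grid, and small independent oracles used to cross-check
# the implementation.

trace_triangle <- function() {
  data.frame(time_s = c(0, 100, 120), temp_c = c(0, -40, 0))
}

# 0 -> -40 over 10 s, hold -40 for 100 s, -40 -> 0 over 20 s
trace_piecewise <- function() {
  data.frame(time_s = c(0, 10, 110, 130), temp_c = c(0, -40, -40, 0))
}

# V-shape: +20 at t=0, nadir -40 at t=100, linear back to +20 at t=160
trace_v <- function(end_time = 160) {
  tt <- c(0, 100, end_time)
  temp_at <- function(t) ifelse(t <= 100, 20 - 0.6 * t, -40 + (t - 100))
  data.frame(time_s = tt, temp_c = temp_at(tt))
}

small_vein_table <- function() {
  tibble::tibble(
    patient_id = rep("P1", 4),
    vein = c("LSPV", "LIPV", "RIPV", "RSPV"),
    tti_s = c(30, 45, NA, 90),
    n_unsuccessful = c(0, 1, 0, 2),
    nadir_temp_c = c(-48, -41, -50, -39),
    erc_status = c("none", "dormant_with_adenosine", "none", "untested"),
    n_bonus = c(0, 0, 1, 0)
  )
}

# Transcription of the published bedside grid (nadir -30..-53 by
# unsuccessful count 0..3, cutoff -7.2, display cap 95 s): for each column,
# the warmest nadir with a finite threshold and the threshold at that nadir;
# thresholds then rise by 10 s per degree colder until they pass 95 s.
expected_decision_grid <- function() {
  first_thr <- list(`0` = c(-37, 10), `1` = c(-39, 5),
                    `2` = c(-42, 10), `3` = c(-44, 5))
  rows <- list()
  for (u in 0:3) {
    start <- first_thr[[as.character(u)]]
    for (nadir in seq(-30, -53)) {
      thr <- start[2] + 10 * (start[1] - nadir)
      rule <- if (nadir > start[1]) "always_test"
      else if (thr > 95) "never_test" else "tti_threshold"
      rows[[length(rows) + 1]] <- tibble::tibble(
        nadir_temp_c = nadir, n_unsuccessful = u, rule = rule,
        tti_threshold_s = if (rule == "tti_threshold") thr else NA_real_)
    }
  }
  dplyr::arrange(dplyr::bind_rows(rows), nadir_temp_c, n_unsuccessful)
}

# brute-force AUC: concordant pairs plus half ties over all pos/neg pairs
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# hand log-rank: observed minus expected over distinct event times
logrank_oracle <- function(time, event, group) {
  g <- as.factor(group)
  lev <- levels(g)[1]
  ut <- sort(unique(time[event]))
  O <- 0; E <- 0; V <- 0
  for (t in ut) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & g == lev)
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & g == lev)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}
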
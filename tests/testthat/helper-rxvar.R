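# shared builders and independent oracles for the test suite

make_rx <- function(patient_id, start_day, days_supplied, daily_ome,
                    year = 2019) {
  tibble::tibble(
    rx_id = paste0(patient_id, "-", seq_along(start_day)),
    patient_id = patient_id,
    start_date = as.Date(paste0(year, "-01-01")) + start_day - 1,
    days_supplied = as.integer(days_supplied),
    total_ome = daily_ome * days_supplied,
    convertible = TRUE
  )
}

# brute-force day-array reconstruction of exposure episodes, independent of
# the interval-merge implementation
oracle_episodes <- function(rx, year, gap_tolerance = 0) {
  jan1 <- as.Date(paste0(year, "-01-01"))
  ylen <- as.integer(as.Date(paste0(year + 1, "-01-01")) - jan1)
  out <- list()
  for (pid in unique(rx$patient_id)) {
    r <- rx[rx$patient_id == pid & rx$days_supplied > 0, ]
    covered <- rep(FALSE, ylen)
    for (i in seq_len(nrow(r))) {
      s <- as.integer(r$start_date[i] - jan1) + 1L
      days <- seq(s, s + r$days_supplied[i] - 1L)
      days <- days[days >= 1 & days <= ylen]
      covered[days] <- TRUE
    }
    if (!any(covered)) next
    runs <- rle(covered)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    cov_runs <- data.frame(start = starts[runs$values],
                           end = ends[runs$values])
    ep_id <- 1L
    ids <- integer(nrow(cov_runs))
    ids[1] <- 1L
    for (i in seq_len(nrow(cov_runs))[-1]) {
      gap <- cov_runs$start[i] - cov_runs$end[i - 1] - 1L
      if (gap > gap_tolerance) ep_id <- ep_id + 1L
      ids[i] <- ep_id
    }
    eps <- do.call(rbind, lapply(split(cov_runs, ids), function(d) {
      data.frame(start = min(d$start), end = max(d$end))
    }))
    eps$total_ome <- 0
    for (i in seq_len(nrow(r))) {
      s <- as.integer(r$start_date[i] - jan1) + 1L
      e <- s + r$days_supplied[i] - 1L
      cs <- max(s, 1L); ce <- min(e, ylen)
      if (ce < cs) next
      frac <- (ce - cs + 1) / r$days_supplied[i]
      j <- which(eps$start <= cs & eps$end >= cs)
      eps$total_ome[j] <- eps$total_ome[j] + r$total_ome[i] * frac
    }
    out[[pid]] <- tibble::tibble(
      patient_id = pid, episode = seq_len(nrow(eps)),
      start_day = eps$start, end_day = eps$end,
      length = eps$end - eps$start + 1L, total_ome = eps$total_ome
    )
  }
  dplyr::bind_rows(out)
}

random_patient_rx <- function(n_patients, year = 2019, max_rx = 6) {
  purrr::map_dfr(seq_len(n_patients), function(i) {
    k <- sample(1:max_rx, 1)
    make_rx(
      patient_id = sprintf("pt%04d", i),
      start_day = sample(-30:400, k, replace = TRUE),
      days_supplied = sample(1:120, k, replace = TRUE),
      daily_ome = runif(k, 5, 200),
      year = year
    )
  })
}

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_practices = 25, practice_size_log_mean = 6.6,
         practice_size_log_sd = 0.3, size_range = c(100, 5000), seed = 421),
    list(...)
  )
  do.call(cohort_config, args)
}
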
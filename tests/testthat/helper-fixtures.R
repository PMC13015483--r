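# Shared test fixtures and small utilities.

# tiny balanced cohort: every participant pre + one post, single profile
tiny_design <- function(n = 6, timepoint = "4hr",
                        groups = c("EE", "CON"), seed = 1) {
  set.seed(seed)
  rows <- list()
  i <- 0L
  for (g in groups) for (k in seq_len(n)) {
    i <- i + 1L
    pid <- sprintf("P%03d", i)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      sample_id = paste0(pid, "_", c("pre", timepoint)),
      participant_id = pid, group = g, timepoint = c("pre", timepoint),
      profile = "middle", age = 25 + (i * 7) %% 40,
      sex = rep(c("F", "M"), length.out = 2)[1],
      bmi = 22 + (i * 3) %% 12, site = "site1", batch = "b1")
  }
  d <- dplyr::bind_rows(rows)
  d$sex <- rep(c("F", "M"), length.out = nrow(d) / 2)[
    match(d$participant_id, unique(d$participant_id))]
  d
}

# adjusted Rand index (Hubert & Arabie) — independent of any clustering code
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  mx <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (mx - expected)
}

# planted trajectory archetype data for FCM recovery tests
planted_trajectories <- function(n_per = 50, noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  arch <- rbind(c(2, 0.5, 0), c(0, 2, 0.5), c(-2, -0.5, 0), c(0.5, 0, 2))
  X <- arch[rep(1:4, each = n_per), ] +
    matrix(rnorm(4 * n_per * 3, sd = noise_sd), 4 * n_per, 3)
  rownames(X) <- sprintf("F%03d", seq_len(nrow(X)))
  colnames(X) <- c("45min", "4hr", "24hr")
  list(X = X, truth = rep(1:4, each = n_per))
}
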
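#' Simulate a three-group acute-exercise cohort design
#'
#' Generates a sample design table for a randomized acute-exercise study
#' with endurance (EE), resistance (RE) and non-exercising control (CON)
#' groups. Every participant contributes a pre-exercise sample plus exactly
#' one post sample; the post timepoint is fixed by the participant's
#' randomized temporal profile (early = 45min, middle = 4hr, late = 24hr).
#' Demographic covariates emulate a sedentary mid-life cohort
#' (age ~ 41 +/- 15 y, BMI ~ 27 +/- 4, ~72% female) and a clinical-site /
#' batch structure.
#'
#' @param n_per_group Named counts of participants per group, e.g.
#'   `c(EE = 21, RE = 24, CON = 12)`.
#' @param profile_weights Three fractions (early, middle, late) summing to 1.
#' @param seed Integer seed; the output is a pure function of the arguments
#'   and the seed.
#' @return A tibble with one row per sample: `sample_id`, `participant_id`,
#'   `group`, `timepoint` (`pre`, `45min`, `4hr`, `24hr`), `profile`, `age`,
#'   `sex`, `bmi`, `site`, `batch`.
#' @export
#' @examples
#' design <- generate_cohort(c(EE = 4, RE = 4, CON = 4), seed = 1)
#' nrow(design) # 24 samples, two per participant
generate_cohort <- function(n_per_group = c(EE = 21, RE = 24, CON = 12),
                            profile_weights = c(early = 1/3, middle = 1/3,
                                                late = 1/3),
                            seed = 1L) {
  groups <- c("EE", "RE", "CON")
  if (is.null(names(n_per_group))) names(n_per_group) <- groups
  if (!all(names(n_per_group) %in% groups)) {
    stop("n_per_group names must be among EE, RE, CON")
  }
  n_per_group <- n_per_group[intersect(groups, names(n_per_group))]
  if (any(n_per_group < 0)) stop("negative participant counts are not allowed")
  if (abs(sum(profile_weights) - 1) > 1e-8) {
    stop("profile_weights must sum to 1")
  }
  set.seed(seed)
  profiles <- c("early", "middle", "late")
  post_of <- c(early = "45min", middle = "4hr", late = "24hr")
  n_total <- sum(n_per_group)
  if (n_total == 0L) {
    return(tibble::tibble(sample_id = character(), participant_id = character(),
                          group = character(), timepoint = character(),
                          profile = character(), age = numeric(),
                          sex = character(), bmi = numeric(),
                          site = character(), batch = character()))
  }
  participants <- purrr::map2_dfr(names(n_per_group), n_per_group,
    function(g, n) {
      if (n == 0L) return(NULL)
      tibble::tibble(group = g, idx = seq_len(n))
    })
  participants$participant_id <- sprintf("P%03d", seq_len(nrow(participants)))
  # deterministic-count profile allocation within group, then shuffled
  participants$profile <- unsplit(lapply(
    split(participants$participant_id, participants$group),
    function(ids) {
      n <- length(ids)
      counts <- floor(profile_weights * n)
      rem <- n - sum(counts)
      if (rem > 0) {
        extra <- order(profile_weights * n - counts,
                       decreasing = TRUE)[seq_len(rem)]
        counts[extra] <- counts[extra] + 1L
      }
      sample(rep(profiles, counts))
    }), participants$group)
  n <- nrow(participants)
  participants$age <- round(pmin(pmax(stats::rnorm(n, 41, 15), 18), 75))
  participants$sex <- ifelse(stats::runif(n) < 0.72, "F", "M")
  participants$bmi <- round(pmin(pmax(stats::rnorm(n, 27.1, 4), 19), 40), 1)
  participants$site <- sample(paste0("site", 1:4), n, replace = TRUE)
  participants$batch <- sample(paste0("batch", 1:3), n, replace = TRUE)
  design <- tidyr::crossing(participants, visit = c("pre", "post")) |>
    dplyr::mutate(
      timepoint = ifelse(.data$visit == "pre", "pre",
                         post_of[.data$profile]),
      sample_id = paste0(.data$participant_id, "_", .data$timepoint)
    ) |>
    dplyr::select("sample_id", "participant_id", "group", "timepoint",
                  "profile", "age", "sex", "bmi", "site", "batch") |>
    dplyr::arrange(.data$participant_id, .data$timepoint != "pre")
  design
}

#' Effect specification for the multi-omic generator
#'
#' Bundles the planted-effect parameters consumed by [generate_omics()].
#' Defaults describe the conditions the downstream modules are exercised
#' under: a modest fraction of features carrying a one-residual-SD
#' difference-in-changes effect, correlated module blocks, trajectory
#' archetypes among responders, non-normal marginals, and a participant
#' random intercept inducing within-person correlation ~0.5.
#'
#' @param n_features_per_ome Named feature counts per ome.
#' @param frac_dd_affected Fraction of features with a planted
#'   difference-in-changes (exercise vs control) effect.
#' @param dd_effect Standardized mean shift of
#'   `(post - pre)_exercise - (post - pre)_control` for affected features.
#' @param sex_effect Standardized male-minus-female shift for sex-affected
#'   features (5% of features).
#' @param n_modules,module_size,module_cor Correlated feature blocks per
#'   ome: count, block size, and within-block correlation in `[0, 1)`.
#' @param n_clusters Number of temporal trajectory archetypes assigned to
#'   dd-affected features.
#' @param skew,kurt Target marginal skewness and excess kurtosis of the
#'   (log-scale) abundances.
#' @param missing_frac Fraction of cells set missing (completely at random)
#'   in the protein and phosphosite omes.
#' @param ri_sd Participant random-intercept SD (residual SD is 1).
#' @param seed Integer seed.
#' @return A list of class `exermap_effect_spec`.
#' @export
effect_spec <- function(n_features_per_ome = c(transcript = 1000,
                                               protein = 400,
                                               phosphosite = 400,
                                               metabolite = 200),
                        frac_dd_affected = 0.05,
                        dd_effect = 1,
                        sex_effect = 1,
                        n_modules = 4,
                        module_size = 50,
                        module_cor = 0.8,
                        n_clusters = 4,
                        skew = 1,
                        kurt = 3,
                        missing_frac = 0,
                        ri_sd = 1,
                        seed = 1L) {
  stopifnot(frac_dd_affected >= 0, frac_dd_affected <= 1,
            missing_frac >= 0, missing_frac <= 1,
            module_cor >= 0, module_cor < 1)
  fleishman_coef(skew, kurt) # validate feasibility up front
  structure(as.list(environment()), class = "exermap_effect_spec")
}
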
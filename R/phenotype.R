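# Athlete phenotype handling: clustering of profiles (PCA + k-means) and the
# per-phenotype agent hyperparameter table.

#' Phenotype category levels
#' @return Character vector of the eight phenotype labels.
#' @export
phenotype_levels <- function() {
  c("Endurance", "Power", "Speed", "Strength", "Technical", "Mixed",
    "Novice", "Elite")
}

# learning rate / discount / adjustment range per phenotype
phenotype_table <- function() {
  tibble(
    phenotype = phenotype_levels(),
    learning_rate = c(0.0008, 0.0012, 0.0015, 0.0010, 0.0006, 0.0009,
                      0.0005, 0.0014),
    discount = c(0.95, 0.90, 0.88, 0.92, 0.96, 0.93, 0.98, 0.87),
    adjustment_range = c(0.15, 0.20, 0.25, 0.18, 0.12, 0.16, 0.10, 0.22)
  )
}

#' Per-phenotype agent configuration overrides
#'
#' Returns the phenotype-specific learning rate and discount factor (plus the
#' tabulated adjustment range): e.g. endurance athletes train with a lower
#' learning rate and longer planning horizon (lr 0.0008, discount 0.95) than
#' speed athletes (lr 0.0015, discount 0.88). Unknown labels fall back to the
#' default configuration with a warning.
#'
#' @param label Phenotype label (see [phenotype_levels()]).
#' @param base An [agent_config()] to override.
#' @return An `agent_config` with `learning_rate` and `discount` set, and an
#'   `adjustment_range` attribute.
#' @examples
#' phenotype_config("Endurance")$learning_rate  # 0.0008
#' @export
phenotype_config <- function(label, base = agent_config()) {
  tbl <- phenotype_table()
  hit <- tbl[tbl$phenotype == label, ]
  if (nrow(hit) != 1) {
    warn(sprintf("unknown phenotype '%s'; using default configuration", label))
    return(base)
  }
  cfg <- modifyList(base, list(learning_rate = hit$learning_rate,
                               discount = hit$discount))
  attr(cfg, "adjustment_range") <- hit$adjustment_range
  cfg
}

# Numeric feature matrix for clustering: the dynamics constants and the
# recovery-compartment parameters of each profile.
profile_feature_matrix <- function(profiles) {
  feats <- purrr::map(profiles, function(p) {
    taus <- vapply(p$compartments, function(cp) cp$tau, numeric(1))
    rmax <- vapply(p$compartments, function(cp) cp$r_max, numeric(1))
    c(adapt_coeff = p$adapt_coeff, adapt_rate = p$adapt_rate,
      fatigue_sens = p$fatigue_sens, k_accum = p$k_accum,
      k_recover = p$k_recover, k_active = p$k_active,
      preferred_load = p$preferred_load,
      tau_mean = mean(taus), rmax_total = sum(rmax))
  })
  do.call(rbind, feats)
}

#' Cluster athlete profiles into phenotype groups
#'
#' Standardizes the profile dynamics features, projects them onto the top
#' principal components retaining `var_frac` of the variance, and runs
#' seeded multi-start k-means on the projection. Labels are stable under an
#' identical seed.
#'
#' @param profiles List of [athlete_profile()].
#' @param k Number of clusters (`k <= length(profiles)`).
#' @param seed Integer seed for the k-means multi-start.
#' @param var_frac Variance fraction retained by the PCA projection.
#' @param nstart k-means multi-start count.
#' @return A list with `labels`, `centroids` (in PC space), `pca` (the
#'   `prcomp` fit) and `n_components`.
#' @export
cluster_phenotypes <- function(profiles, k, seed = 1L, var_frac = 0.9,
                               nstart = 10L) {
  if (k > length(profiles)) {
    abort("k must not exceed the number of profiles",
          class = "loadctrl_invalid_input")
  }
  X <- profile_feature_matrix(profiles)
  keep <- apply(X, 2, function(col) sd(col) > 0)
  Xs <- scale(X[, keep, drop = FALSE])
  if (!ncol(Xs)) Xs <- matrix(0, nrow(X), 1)
  pca <- prcomp(Xs, center = FALSE, scale. = FALSE)
  totvar <- sum(pca$sdev^2)
  if (totvar > 0) {
    cum <- cumsum(pca$sdev^2) / totvar
    m <- max(1L, which(cum >= var_frac)[1])
    proj <- pca$x[, seq_len(m), drop = FALSE]
  } else {
    m <- 1L
    proj <- matrix(0, nrow(Xs), 1)
  }
  km <- with_stream(rng_stream(seed),
                    kmeans(proj, centers = k, nstart = nstart))
  list(labels = km$cluster, centroids = km$centers, pca = pca,
       n_components = m)
}
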
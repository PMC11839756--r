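#' Simulation configuration for one group
#'
#' Defines a latent-factor generative model for a cohort group: per-subject
#' covariates (age, sex, intracranial volume), per-ROI mean `mu_r` and
#' noise SD `sigma_r` (mm^3), covariate slopes `beta_r`, and a loading
#' matrix `Lambda` (ROIs x latent factors) that induces inter-regional
#' covariance. Volumes are generated as
#' `mu_r + beta_r . (c - E[c]) + Lambda[r, ] . f + eps`, with standard
#' normal factors `f` shared within subject and `eps ~ N(0, sigma_r^2)`.
#' Covariates are centered at their population means in generation so
#' `mu_r` is the group mean. With one factor, loading `lambda` on two ROIs
#' with unit noise, the implied inter-ROI correlation is
#' `lambda^2 / (lambda^2 + 1)`.
#'
#' @param n Number of subjects (>= 8).
#' @param group Group label.
#' @param mu Named numeric vector of ROI means (mm^3).
#' @param sigma Noise SDs, same length/names as `mu`, all > 0.
#' @param beta ROI x covariate slope matrix (columns `age`, `sex`, `icv`);
#'   `NULL` for no covariate effects.
#' @param lambda ROI x factor loading matrix; `NULL` for independence.
#' @param covariates List with `age_mean`, `age_sd`, `sex_p`, `icv_mean`,
#'   `icv_sd`.
#' @param seed Integer seed (mandatory).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n, group, mu, sigma, beta = NULL,
                              lambda = NULL,
                              covariates = list(age_mean = 64.7,
                                                age_sd = 11.0,
                                                sex_p = 0.5,
                                                icv_mean = 1.45e6,
                                                icv_sd = 1.4e5),
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n >= 8, length(mu) == length(sigma), all(sigma > 0),
            !is.null(names(mu)))
  if (!is.null(beta)) {
    beta <- as.matrix(beta)
    stopifnot(nrow(beta) == length(mu), all(is.finite(beta)))
  }
  if (!is.null(lambda)) {
    lambda <- as.matrix(lambda)
    stopifnot(nrow(lambda) == length(mu), all(is.finite(lambda)))
  }
  structure(list(n = as.integer(n), group = group, mu = mu, sigma = sigma,
                 beta = beta, lambda = lambda, covariates = covariates,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a cohort group
#'
#' Deterministic given the config seed.
#'
#' @param cfg A [simulation_config()]; or a list of them, whose cohorts are
#'   concatenated (subject ids stay unique via the group label).
#' @return A `cohort_table`.
#' @export
simulate_cohort <- function(cfg) {
  if (!inherits(cfg, "simulation_config") && is.list(cfg)) {
    tabs <- lapply(cfg, simulate_cohort)
    out <- do.call(rbind, lapply(tabs, as.data.frame))
    return(cohort_table(out, volume_cols = volume_cols(tabs[[1]]),
                        allow_negative = TRUE))
  }
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n <- cfg$n
  cv <- cfg$covariates
  age <- stats::rnorm(n, cv$age_mean, cv$age_sd)
  sex <- stats::rbinom(n, 1, cv$sex_p)
  icv <- stats::rnorm(n, cv$icv_mean, cv$icv_sd)
  cc <- cbind(age = age - cv$age_mean, sex = sex - cv$sex_p,
              icv = icv - cv$icv_mean)
  p <- length(cfg$mu)
  Y <- matrix(rep(cfg$mu, each = n), nrow = n)
  if (!is.null(cfg$beta)) {
    Y <- Y + cc[, colnames(cfg$beta), drop = FALSE] %*% t(cfg$beta)
  }
  if (!is.null(cfg$lambda)) {
    f <- matrix(stats::rnorm(n * ncol(cfg$lambda)), nrow = n)
    Y <- Y + f %*% t(cfg$lambda)
  }
  Y <- Y + matrix(stats::rnorm(n * p, sd = rep(cfg$sigma, each = n)),
                  nrow = n)
  tab <- data.frame(subject_id = sprintf("%s%03d", cfg$group, seq_len(n)),
                    group = cfg$group, age = age, sex = sex, icv = icv,
                    check.names = FALSE)
  tab[names(cfg$mu)] <- as.data.frame(Y)
  cohort_table(tab, volume_cols = names(cfg$mu), allow_negative = TRUE)
}

# Node means and SDs on the scale of published volumetric tables for the
# 22-node network (geniculate = LGN + MGN merged; SDs combined in
# quadrature).
.preset_scale <- function() {
  nodes <- network_nodes()
  mu <- c(
    "left ventral" = 2571, "left anteroventral" = 108, "left medial" = 1381,
    "left lateral" = 116, "left pulvinar" = 1666, "left geniculate" = 332,
    "right ventral" = 2485, "right anteroventral" = 116,
    "right medial" = 1364, "right lateral" = 110, "right pulvinar" = 1647,
    "right geniculate" = 324,
    "left frontal" = 55288, "left parietal" = 47449,
    "left temporal" = 48159, "left occipital" = 20261,
    "left cingulate" = 8717,
    "right frontal" = 56053, "right parietal" = 48919,
    "right temporal" = 46923, "right occipital" = 21085,
    "right cingulate" = 8196)
  sd <- c(
    "left ventral" = 358, "left anteroventral" = 23, "left medial" = 173,
    "left lateral" = 27, "left pulvinar" = 235, "left geniculate" = 46,
    "right ventral" = 343, "right anteroventral" = 23,
    "right medial" = 170, "right lateral" = 24, "right pulvinar" = 231,
    "right geniculate" = 40,
    "left frontal" = 5561, "left parietal" = 5102, "left temporal" = 4940,
    "left occipital" = 2628, "left cingulate" = 1301,
    "right frontal" = 5862, "right parietal" = 4863,
    "right temporal" = 4594, "right occipital" = 2627,
    "right cingulate" = 1118)
  list(mu = mu[nodes], sd = sd[nodes])
}

#' Two-group cortical-thalamic preset cohort
#'
#' Generates an ET-like and an HC-like group over the 22 network nodes,
#' with node means and SDs on the scale of published cortical-thalamic
#' volumetrics and realistic covariate effects (mild age atrophy, sex
#' dimorphism, allometric ICV scaling). The covariance structure has two
#' layers:
#'
#' * two domain factors — a thalamic factor loading all thalamic groups
#'   and a cortical factor loading all lobes, with the ventral and
#'   pulvinar nodes bridging both and mild cross-domain loadings
#'   integrating the two blocks;
#' * one bilateral homolog factor per left/right node pair, identical in
#'   both groups.
#'
#' The HC group uses the base domain loadings; the ET-like group's domain
#' loadings are the base times `contrast`, while the homolog factors are
#' never scaled. At `contrast < 1` the patient-like group therefore keeps
#' its strong homologous-pair correlations but loses cortico-thalamic
#' integration — its network is weaker, longer-pathed and breaks into
#' modules, while the control-like network stays dense and integrated.
#'
#' @param contrast Loading ratio in (0, 1]; 1 makes the groups
#'   exchangeable.
#' @param n1,n2 Group sizes (defaults 109 ET-like, 81 HC-like).
#' @param seed Integer seed.
#' @param base_loading Within-domain loading of the HC group, as a
#'   fraction of each node's scale SD (default 0.9).
#' @param bridge_loading Cortical-factor loading of the ventral/pulvinar
#'   bridge nodes, same units (default 0.5).
#' @param cross_loading Mild opposite-domain loading integrating the two
#'   blocks (default 0.4).
#' @param pair_loading Bilateral homolog factor loading, unscaled by
#'   `contrast` (default 0.8).
#' @param noise_sd Idiosyncratic noise SD as a fraction of each node's
#'   scale SD (default 0.4).
#' @param beta_scale Multiplier on the default covariate slopes (0 turns
#'   covariate effects off).
#' @param labels Group labels, `c(group1, group2)` with group1 the ET-like
#'   (weaker-loading) group.
#' @return A `cohort_table` with both groups.
#' @export
preset_et_hc <- function(contrast = 0.5, n1 = 109L, n2 = 81L, seed = 1L,
                         base_loading = 0.9, bridge_loading = 0.5,
                         cross_loading = 0.4, pair_loading = 0.8,
                         noise_sd = 0.4, beta_scale = 1,
                         labels = c("ET", "HC")) {
  stopifnot(contrast > 0, contrast <= 1)
  sc <- .preset_scale()
  nodes <- names(sc$mu)
  thal <- nodes %in% network_nodes()[1:12]
  bridge <- nodes %in% c("left ventral", "right ventral", "left pulvinar",
                         "right pulvinar")
  lam <- matrix(0, length(nodes), 2,
                dimnames = list(nodes, c("thalamic", "cortical")))
  lam[thal, "thalamic"] <- base_loading * sc$sd[thal]
  lam[!thal, "cortical"] <- base_loading * sc$sd[!thal]
  lam[bridge, "cortical"] <- bridge_loading * sc$sd[bridge]
  lam[!thal, "thalamic"] <- cross_loading * sc$sd[!thal]
  lam[thal & !bridge, "cortical"] <- cross_loading * sc$sd[thal & !bridge]
  pairs <- unique(sub("^(left|right) ", "", nodes))
  pair_lam <- matrix(0, length(nodes), length(pairs),
                     dimnames = list(nodes, pairs))
  for (b in pairs) {
    both <- paste(c("left", "right"), b)
    pair_lam[both, b] <- pair_loading * sc$sd[both]
  }
  beta <- cbind(age = -0.002 * sc$mu, sex = 0.02 * sc$mu,
                icv = 0.7 * sc$mu / 1.45e6) * beta_scale
  cfg1 <- simulation_config(n = n1, group = labels[1], mu = sc$mu,
                            sigma = noise_sd * sc$sd, beta = beta,
                            lambda = cbind(lam * contrast, pair_lam),
                            seed = seed)
  cfg2 <- simulation_config(n = n2, group = labels[2], mu = sc$mu,
                            sigma = noise_sd * sc$sd, beta = beta,
                            lambda = cbind(lam, pair_lam),
                            seed = seed + 1L)
  simulate_cohort(list(cfg1, cfg2))
}

#' Write a cohort table as TSV
#'
#' @param cohort A `cohort_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  utils::write.table(as.data.frame(cohort), path, sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
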
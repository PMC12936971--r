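#' Specify a synthetic multisite cohort
#'
#' Bundles and validates the parameters of the synthetic-cohort generator.
#' The generator emulates the statistical structure the downstream pipeline
#' assumes in a multisite pediatric case-control morphometry study: smooth
#' nonlinear age effects, sex effects and site offsets on regional gray-matter
#' values, module-structured coupling between regions (so similarity-network
#' edges are informative), `k_true` latent case subgroups that decouple
#' designated node sets from their module factors, and biotype-graded symptom
#' scores on a 0-1 scale.
#'
#' @param n_controls,n_cases Subject counts per group.
#' @param n_sites Number of acquisition sites.
#' @param n_regions Number of brain regions (parcels); at least 8.
#' @param n_samples_per_region Number of value draws per (subject, region);
#'   these play the role of within-parcel voxel samples.
#' @param age_range Length-2 numeric, years; must lie within \[6, 18\].
#' @param male_fraction Proportion male, either one value for both groups or
#'   `c(control, case)`.
#' @param k_true Number of planted case biotypes (>= 1).
#' @param effect_size Non-negative decoupling intensity. 0 makes cases
#'   generatively identical to controls. With `s = effect_size / 3`, the
#'   planted coupling disruption replaces a fraction `min(1, s)` of the
#'   shared module-factor variance on each biotype's node set with
#'   independent subject-specific noise of standard deviation
#'   `tau * (1 + s)` — regions are both desynchronized from their community
#'   and excessively variable, so at `effect_size = 3` the disruption is a
#'   complete factor replacement with doubled idiosyncratic spread.
#' @param seed Integer seed; all generator output is reproducible given it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_controls = 300L, n_cases = 300L, n_sites = 4L,
                        n_regions = 60L, n_samples_per_region = 200L,
                        age_range = c(6, 18), male_fraction = c(0.60, 0.76),
                        k_true = 3L, effect_size = 3, seed = 1L) {
  stopifnot(n_controls >= 1, n_cases >= 1, n_sites >= 1,
            n_samples_per_region >= 10, length(age_range) == 2)
  if (n_regions < 8) stop("n_regions must be at least 8")
  if (k_true < 1) stop("k_true must be at least 1")
  if (effect_size < 0) stop("effect_size must be non-negative")
  if (k_true > n_cases) stop("k_true cannot exceed n_cases")
  if (n_regions < 2 * k_true)
    stop("n_regions must be at least 2 * k_true so biotype node sets are disjoint")
  if (age_range[1] < 6 || age_range[2] > 18 || age_range[1] >= age_range[2])
    stop("age_range must be an increasing interval within [6, 18]")
  if (length(male_fraction) == 1) male_fraction <- rep(male_fraction, 2)
  stopifnot(all(male_fraction >= 0 & male_fraction <= 1))
  structure(list(n_controls = as.integer(n_controls),
                 n_cases = as.integer(n_cases),
                 n_sites = as.integer(n_sites),
                 n_regions = as.integer(n_regions),
                 n_samples_per_region = as.integer(n_samples_per_region),
                 age_range = as.numeric(age_range),
                 male_fraction = as.numeric(male_fraction),
                 k_true = as.integer(k_true),
                 effect_size = as.numeric(effect_size),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Quasi-uniform node coordinates on the unit sphere
#'
#' Fibonacci lattice: `n` points spread quasi-uniformly over the sphere, so
#' rotation-based spatial nulls behave well.
#'
#' @param n Number of points.
#' @return `n` x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Spatially contiguous module labels from seeded k-means on sphere coords.
make_modules <- function(coords, n_modules, seed) {
  with_seed(seed, {
    km <- suppressWarnings(
      stats::kmeans(coords, centers = n_modules, nstart = 10, iter.max = 100))
    km$cluster
  })
}

#' Generate a synthetic multisite cohort
#'
#' Draws a full cohort under the generative model described in
#' [cohort_spec()]: per-subject, per-region positive morphometry samples whose
#' latent region means share module-level factors, plus a subject table,
#' node geometry, and the planted ground truth.
#'
#' Controls' latent region means follow
#' `b0_r + f_r(age) + c_r * sex + s_site + g_r * a_{m(r)}`, with `f_r` a
#' smooth logistic age curve and `a_m` a per-subject module factor. Cases of
#' biotype `k` have the shared-factor term on node set `S_k` partially
#' replaced by independent noise, so the planted effect
#' lives in inter-regional coupling — the space morphometric similarity
#' networks measure — rather than in regional means.
#'
#' @param spec A [cohort_spec()].
#' @param template Optional `ground_truth` element of a previously generated
#'   cohort. When given, the new cohort reuses that cohort's region
#'   parameters, module structure, and planted biotype node sets (a
#'   "same-process" validation cohort); new subjects, site offsets, and site
#'   noise scales are still drawn under `spec$seed`. Requires matching
#'   `n_regions` and `k_true`.
#' @return List with elements:
#'   * `cohort`: data.frame (subject_id, age, sex, site, group,
#'     true_biotype, inattention, hyperactivity); `true_biotype` is `NA`
#'     for controls; symptom scores lie in \[0, 1\].
#'   * `samples`: named list (by subject_id) of regions x samples matrices
#'     of positive values.
#'   * `geometry`: data.frame (region_index, x, y, z, true_module);
#'     `region_index` is 1-based.
#'   * `ground_truth`: list with `biotype_nodes` (list of region-index sets),
#'     `modules`, and generative parameters.
#' @export
generate_cohort <- function(spec, template = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  R <- spec$n_regions
  coords <- fibonacci_sphere(R)
  if (is.null(template)) {
    n_modules <- max(2L, min(6L, R %/% 10L))
    modules <- make_modules(coords, n_modules,
                            derive_seed(spec$seed, "modules"))
  } else {
    rp <- template$region_params
    if (length(template$modules) != R)
      stop("template n_regions does not match spec")
    if (length(template$biotype_nodes) != spec$k_true)
      stop("template k_true does not match spec")
    modules <- template$modules
    n_modules <- length(unique(modules))
  }
  geometry <- data.frame(region_index = seq_len(R),
                         x = coords[, 1], y = coords[, 2], z = coords[, 3],
                         true_module = modules)

  with_seed(derive_seed(spec$seed, "cohort"), {
    # Region-level generative parameters. Regions within a module share
    # their baseline, growth curve, loading, and sample-variance profile up
    # to small jitter: morphometric-similarity modules are sets of regions
    # with common maturational and architectonic profiles, and this shared
    # structure is what makes MSN edges informative.
    if (is.null(template)) {
      b_module <- stats::runif(n_modules, 4.5, 6.5)
      b0 <- b_module[modules] + stats::rnorm(R, 0, 0.05)
      g <- 1 + stats::rnorm(R, 0, 0.03)          # module-factor loadings
      amp_m <- stats::rnorm(n_modules, 0, 0.25)  # module age amplitudes
      amp <- amp_m[modules] + stats::rnorm(R, 0, 0.05)
      mid_m <- stats::runif(n_modules, 9, 13)    # module age midpoints
      mid <- mid_m[modules] + stats::rnorm(R, 0, 0.5)
      sex_m <- stats::rnorm(n_modules, 0, 0.08)
      sex_eff <- sex_m[modules] + stats::rnorm(R, 0, 0.02)
      sigma_m <- stats::runif(n_modules, 0.30, 0.50)  # module sample SD
      sigma_r <- sigma_m[modules] * (1 + stats::rnorm(R, 0, 0.03))
      tau <- 0.35                                # module-factor SD
    } else {
      b0 <- rp$b0; g <- rp$g; amp <- rp$amp; mid <- rp$mid
      sex_eff <- rp$sex_eff; sigma_r <- rp$sigma_r; tau <- rp$tau
    }
    site_offset <- stats::rnorm(spec$n_sites, 0, 0.15)
    site_scale <- stats::runif(spec$n_sites, 0.9, 1.1)

    n <- spec$n_controls + spec$n_cases
    group <- rep(c("control", "case"), c(spec$n_controls, spec$n_cases))
    site <- paste0("site", 1 + (sample.int(n) %% spec$n_sites))
    age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    sex <- c(stats::rbinom(spec$n_controls, 1, spec$male_fraction[1]),
             stats::rbinom(spec$n_cases, 1, spec$male_fraction[2]))

    # planted biotypes: equal sizes, shuffled; disjoint node sets
    bt <- rep(NA_integer_, n)
    bt[group == "case"] <-
      sample(rep_len(seq_len(spec$k_true), spec$n_cases))
    if (is.null(template)) {
      set_size <- max(2L, R %/% (2L * spec$k_true))
      perm <- sample.int(R)
      biotype_nodes <- lapply(seq_len(spec$k_true), function(k)
        sort(perm[((k - 1) * set_size + 1):(k * set_size)]))
    } else {
      biotype_nodes <- template$biotype_nodes
    }

    es_rel <- spec$effect_size / 3
    w_dec <- min(1, es_rel)                      # decoupling weight
    eta_sd <- tau * (1 + es_rel)                 # idiosyncratic noise SD

    f_age <- function(a) {
      curve <- outer(a, seq_len(R), function(aa, r)
        amp[r] * stats::plogis((aa - mid[r]) / 1.5))
      ref <- amp * stats::plogis((12 - mid) / 1.5)
      sweep(curve, 2, ref)                       # centered at age 12
    }
    fa <- f_age(age)
    site_idx <- as.integer(sub("site", "", site))

    samples <- vector("list", n)
    subject_id <- sprintf("sub%04d", seq_len(n))
    names(samples) <- subject_id
    for (s in seq_len(n)) {
      a_m <- stats::rnorm(n_modules, 0, tau)
      coupling <- g * a_m[modules]
      if (group[s] == "case" && w_dec > 0) {
        nodes <- biotype_nodes[[bt[s]]]
        eta <- stats::rnorm(length(nodes), 0, eta_sd)
        coupling[nodes] <- g[nodes] *
          (sqrt(1 - w_dec) * a_m[modules[nodes]] + sqrt(w_dec) * eta)
      }
      mu <- b0 + fa[s, ] + sex_eff * sex[s] + site_offset[site_idx[s]] +
        coupling + stats::rnorm(R, 0, 0.05)
      sd_s <- sigma_r * site_scale[site_idx[s]]
      vals <- matrix(stats::rnorm(R * spec$n_samples_per_region, mu, sd_s),
                     nrow = R)
      samples[[s]] <- pmax(vals, 1e-6)
    }

    # biotype-graded symptom scores, biotype 1 most severe on both scales
    inatt_mu <- c(0.25, seq(0.77, 0.71, length.out = spec$k_true))
    hyper_mu <- c(0.22, seq(0.68, 0.60, length.out = spec$k_true))
    idx <- ifelse(group == "control", 1L, bt + 1L)
    inattention <- pmin(1, pmax(0, stats::rnorm(n, inatt_mu[idx], 0.16)))
    hyperactivity <- pmin(1, pmax(0, stats::rnorm(n, hyper_mu[idx], 0.22)))

    cohort <- data.frame(subject_id = subject_id, age = age, sex = sex,
                         site = site, group = group, true_biotype = bt,
                         inattention = inattention,
                         hyperactivity = hyperactivity,
                         stringsAsFactors = FALSE)

    list(cohort = cohort, samples = samples, geometry = geometry,
         ground_truth = list(biotype_nodes = biotype_nodes,
                             modules = modules, decoupling_weight = w_dec,
                             decoupling_noise_sd = eta_sd,
                             region_params = list(b0 = b0, g = g, amp = amp,
                                                  mid = mid,
                                                  sex_eff = sex_eff,
                                                  sigma_r = sigma_r,
                                                  tau = tau),
                             site_offset = site_offset,
                             site_scale = site_scale))
  })
}

#' Generate spatially smooth annotation maps
#'
#' Draws node-wise maps as Gaussian random fields on the sphere with
#' covariance decaying in great-circle distance, standing in for receptor
#' density or meta-analytic task maps. With `link`, each map is mixed with
#' the (standardized) target so its expected spatial correlation equals
#' `link$rho`.
#'
#' @param geometry Node geometry as returned by [generate_cohort()].
#' @param n_maps Number of maps.
#' @param smoothness Correlation length (radians of arc) of the field; > 0.
#'   Values near 0 give (numerically) independent node values.
#' @param link Optional `list(target = <values>, rho = <0 <= rho < 1>)`.
#' @param seed Integer seed.
#' @return data.frame with `region_index` and one column per map.
#' @export
generate_annotation_maps <- function(geometry, n_maps, smoothness,
                                     link = NULL, seed = 1L) {
  if (smoothness <= 0) stop("smoothness must be positive")
  if (!is.null(link)) {
    stopifnot(is.list(link), length(link$target) == nrow(geometry))
    if (link$rho < 0 || link$rho >= 1) stop("link rho must be in [0, 1)")
  }
  coords <- as.matrix(geometry[, c("x", "y", "z")])
  gram <- coords %*% t(coords)
  gram[gram > 1] <- 1; gram[gram < -1] <- -1
  d <- acos(gram)                                # great-circle distance
  K <- exp(-(d / smoothness)^2)
  L <- chol(K + diag(1e-8, nrow(K)))
  with_seed(seed, {
    Z <- t(L) %*% matrix(stats::rnorm(nrow(K) * n_maps), nrow(K), n_maps)
    Z <- scale(Z)
    if (!is.null(link)) {
      tgt <- as.numeric(scale(link$target))
      Z <- link$rho * tgt + sqrt(1 - link$rho^2) * Z
    }
    out <- data.frame(region_index = geometry$region_index)
    colnames_maps <- sprintf("map%03d", seq_len(n_maps))
    for (j in seq_len(n_maps)) out[[colnames_maps[j]]] <- Z[, j]
    out
  })
}
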
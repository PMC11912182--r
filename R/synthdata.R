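#' The 20-site cohort composition table
#'
#' Returns the per-site composition of the reference multi-site autism/TD
#' cohort: site id, number of autism and TD participants, mean age and the
#' fraction of male participants. At `scale = 1` this is the full 20-site,
#' 870-participant table (403 autism / 467 TD); at `scale < 1` each cell is
#' scaled down and floored, keeping at least one participant in every
#' non-empty cell so the site x label stratification structure survives
#' desk-scale experiments.
#'
#' @param scale fraction in (0, 1] applied to every (site, label) cell.
#' @return data.frame with columns `site`, `n_autism`, `n_td`, `mean_age`,
#'   `male_frac`.
#' @examples
#' tab <- abideSiteTable()
#' sum(tab$n_autism + tab$n_td)  # 870
#' @export
abideSiteTable <- function(scale = 1) {
  stopifnot2(is.numeric(scale) && length(scale) == 1L && scale > 0 && scale <= 1,
             "scale must be a fraction in (0, 1]")
  tab <- data.frame(
    site = c("PITT", "OLIN", "OHSU", "NYU", "SBL", "SDSU", "STANFORD",
             "TRINITY", "UCLA_2", "UM_1", "UM_2", "USM", "YALE", "CALTECH",
             "CMU", "KKI", "LEUVEN_1", "LEUVEN_2", "MAX_MUN", "UCLA_1"),
    n = c(50, 28, 25, 172, 26, 27, 25, 44, 21, 86, 34, 67, 41, 15, 11, 33,
          28, 28, 45, 64),
    mean_age = c(18.50, 17.04, 10.81, 15.33, 33.77, 14.36, 9.99, 17.03,
                 12.47, 13.77, 16.01, 22.59, 13.31, 26.79, 26.82, 10.31,
                 22.43, 14.17, 26.49, 13.35),
    n_male = c(43, 23, 25, 136, 26, 21, 18, 44, 19, 61, 32, 67, 25, 10, 7,
               24, 28, 21, 41, 55),
    n_autism = c(24, 14, 12, 74, 12, 8, 12, 19, 11, 34, 13, 43, 22, 5, 6,
                 12, 14, 12, 19, 37),
    stringsAsFactors = FALSE
  )
  tab$n_td <- tab$n - tab$n_autism
  tab$male_frac <- tab$n_male / tab$n
  if (scale < 1) {
    tab$n_autism <- ifelse(tab$n_autism > 0L,
                           pmax(1L, floor(tab$n_autism * scale)), 0L)
    tab$n_td <- ifelse(tab$n_td > 0L, pmax(1L, floor(tab$n_td * scale)), 0L)
  }
  tab[, c("site", "n_autism", "n_td", "mean_age", "male_frac")]
}

#' Configuration of the synthetic cohort generator
#'
#' Bundles and validates the parameters that define a synthetic multi-site
#' cohort: atlas size, per-site composition, how many connectivity edges and
#' structural features carry a planted class effect, the standardized effect
#' size, and the site-heterogeneity and residual noise scales.
#'
#' The class effect on connectivity is applied in Fisher-z space and mapped
#' back through `tanh`, so correlations stay inside (-1, 1); the planted
#' standardized mean difference between classes is approximately
#' `effect_size_d`. Site heterogeneity is an additive per-feature offset
#' drawn once per site with standard deviation `site_shift_sd`.
#'
#' @param n_rois number of atlas regions (edge space is `n_rois (n_rois-1)/2`).
#' @param n_timepoints BOLD series length used when time-series are emitted
#'   (and for the motion-outlier percentage phenotype).
#' @param site_table data.frame with columns `site`, `n_autism`, `n_td`
#'   (optionally `mean_age`, `male_frac`); defaults to [abideSiteTable()].
#' @param n_informative_edges,n_informative_struct planted feature counts.
#' @param effect_size_d standardized mean difference on planted features.
#' @param site_shift_sd,noise_sd site offset and residual scales (Fisher-z
#'   units for edges).
#' @param n_cortical,n_noncortical structural atlas sizes; the structural
#'   vector has length `n_cortical * 9 + n_noncortical * 7` (1417 at the
#'   defaults).
#' @param include_timeseries also simulate ROI x T BOLD series per subject.
#' @param qc_label_leak additive shift of the motion-outlier count for the
#'   autism class (0 = QC phenotypes independent of label; ablation knob).
#' @param seed integer seed; identical configurations reproduce cohorts
#'   bit-identically.
#' @return a `GenerationConfig` list.
#' @export
generationConfig <- function(n_rois = 200L, n_timepoints = 150L,
                             site_table = abideSiteTable(),
                             n_informative_edges = 50L,
                             n_informative_struct = 20L,
                             effect_size_d = 0.8,
                             site_shift_sd = 0.15, noise_sd = 0.3,
                             n_cortical = 68L, n_noncortical = 115L,
                             include_timeseries = FALSE,
                             qc_label_leak = 0, seed = 1L) {
  stopifnot2(n_rois >= 2, "n_rois must be >= 2")
  stopifnot2(effect_size_d >= 0, "effect_size_d must be >= 0")
  stopifnot2(all(c("site", "n_autism", "n_td") %in% colnames(site_table)) &&
               nrow(site_table) > 0L, "site_table must be non-empty")
  if (any(site_table$n_autism + site_table$n_td <= 0L))
    stop("site_table contains a site with zero members", call. = FALSE)
  n_edges <- n_rois * (n_rois - 1L) / 2
  if (n_informative_edges > n_edges)
    stop("n_informative_edges exceeds the edge space (", n_edges, ")",
         call. = FALSE)
  n_struct <- n_cortical * 9L + n_noncortical * 7L
  if (n_informative_struct > n_struct)
    stop("n_informative_struct exceeds the structural space", call. = FALSE)
  if (is.null(site_table$mean_age)) site_table$mean_age <- 15
  if (is.null(site_table$male_frac)) site_table$male_frac <- 0.8
  structure(list(
    n_rois = as.integer(n_rois), n_timepoints = as.integer(n_timepoints),
    site_table = site_table,
    n_informative_edges = as.integer(n_informative_edges),
    n_informative_struct = as.integer(n_informative_struct),
    effect_size_d = effect_size_d, site_shift_sd = site_shift_sd,
    noise_sd = noise_sd, n_cortical = as.integer(n_cortical),
    n_noncortical = as.integer(n_noncortical),
    include_timeseries = isTRUE(include_timeseries),
    qc_label_leak = qc_label_leak, seed = as.integer(seed)
  ), class = "GenerationConfig")
}

#' Generate a synthetic multi-site cohort with planted class effects
#'
#' Draws one cohort according to a [generationConfig()]: per-site sample
#' counts match the site table exactly; a fixed random subset of
#' connectivity edges and structural features receives an additive
#' between-class shift of approximately `effect_size_d` within-class
#' standard deviations; every feature additionally receives a per-site
#' offset shared by all participants of a site. Connectivity is built in
#' Fisher-z space around a common group-level backbone and mapped through
#' `tanh`, yielding symmetric unit-diagonal matrices with entries in
#' (-1, 1).
#'
#' @param cfg a `GenerationConfig`.
#' @return a [Cohort-class]; its [groundTruth()] records the planted edge
#'   and structural feature indices (upper-triangle / flattened indexing)
#'   and the per-site offset vectors.
#' @export
generateCohort <- function(cfg) {
  stopifnot2(inherits(cfg, "GenerationConfig"), "cfg must be a GenerationConfig")
  withSeed(cfg$seed, {
    st <- cfg$site_table
    n_edges <- cfg$n_rois * (cfg$n_rois - 1L) / 2
    n_struct <- cfg$n_cortical * 9L + cfg$n_noncortical * 7L

    planted_e <- sort(sample.int(n_edges, cfg$n_informative_edges))
    planted_s <- sort(sample.int(n_struct, cfg$n_informative_struct))
    base_z <- stats::rnorm(n_edges, 0, 0.25)
    base_s <- stats::rnorm(n_struct, 0, 1)

    site_off_e <- lapply(seq_len(nrow(st)), function(i)
      stats::rnorm(n_edges, 0, cfg$site_shift_sd))
    site_off_s <- lapply(seq_len(nrow(st)), function(i)
      stats::rnorm(n_struct, 0, cfg$site_shift_sd))
    names(site_off_e) <- names(site_off_s) <- st$site

    sigma_within <- sqrt(cfg$noise_sd^2 + cfg$site_shift_sd^2)
    delta <- cfg$effect_size_d * sigma_within

    rows <- list(); fc <- list(); ts <- list()
    struct <- matrix(0, sum(st$n_autism + st$n_td), n_struct)
    idx <- utils::combn(cfg$n_rois, 2L)  # column-per-edge, row-major (i<j)
    # combn emits (1,2),(1,3),...,(1,n),(2,3),...: already the fixed order
    k <- 0L
    for (s in seq_len(nrow(st))) {
      labs <- c(rep("autism", st$n_autism[s]), rep("td", st$n_td[s]))
      for (lab in labs) {
        k <- k + 1L
        id <- sprintf("%s_%04d", st$site[s], k)
        sgn <- if (lab == "autism") 0.5 else -0.5
        z <- base_z + site_off_e[[s]] + stats::rnorm(n_edges, 0, cfg$noise_sd)
        z[planted_e] <- z[planted_e] + sgn * delta
        m <- matrix(0, cfg$n_rois, cfg$n_rois)
        m[t(idx)[, c(2L, 1L)]] <- tanh(z)   # fill lower triangle (j,i)
        m <- m + t(m); diag(m) <- 1
        fc[[id]] <- m
        sv <- base_s + site_off_s[[s]] + stats::rnorm(n_struct, 0, cfg$noise_sd)
        sv[planted_s] <- sv[planted_s] + sgn * delta
        struct[k, ] <- sv
        age <- max(6, stats::rnorm(1, st$mean_age[s], 3))
        sex <- if (stats::runif(1) < st$male_frac[s]) "M" else "F"
        num <- stats::rpois(1, 5) +
          if (lab == "autism") cfg$qc_label_leak else 0
        rows[[k]] <- data.frame(
          id = id, site = st$site[s], label = lab, age = age, sex = sex,
          fiq = stats::rnorm(1, 105, 15), num = num,
          pec = 100 * num / cfg$n_timepoints,
          rat = stats::runif(1, 0.6, 1), stringsAsFactors = FALSE)
        if (cfg$include_timeseries)
          ts[[id]] <- generateTimeseries(m, cfg$n_timepoints,
                                         seed = NULL)
      }
    }
    pheno <- do.call(rbind, rows)
    rownames(struct) <- pheno$id
    colnames(struct) <- structuralFeatureIds(cfg$n_cortical, cfg$n_noncortical)
    methods::new("Cohort",
      pheno = S4Vectors::DataFrame(pheno), fc = fc, timeseries = ts,
      struct = struct,
      groundTruth = list(planted_edge_ids = planted_e,
                         planted_struct_ids = planted_s,
                         per_site_offsets = list(edges = site_off_e,
                                                 struct = site_off_s)))
  })
}

#' Simulate BOLD-like time-series with a target correlation structure
#'
#' Draws a Gaussian ROI x T series whose empirical correlation converges to
#' `target_corr` as T grows. A target that is not positive semidefinite is
#' projected to the nearest PSD correlation matrix (eigenvalue clipping plus
#' diagonal rescaling) with a warning.
#'
#' @param target_corr symmetric unit-diagonal correlation matrix.
#' @param T number of timepoints (>= 2).
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return ROI x T numeric matrix.
#' @export
generateTimeseries <- function(target_corr, T, seed = NULL) {
  stopifnot2(isSymmetricTol(target_corr, 1e-8), "target_corr must be symmetric")
  stopifnot2(T >= 2, "T must be >= 2")
  eg <- eigen(target_corr, symmetric = TRUE)
  if (min(eg$values) < -1e-8) {
    warning("target correlation is not positive semidefinite; ",
            "projecting to the nearest PSD correlation matrix")
    v <- pmax(eg$values, 0)
    m <- eg$vectors %*% (v * t(eg$vectors))
    d <- sqrt(pmax(diag(m), 1e-12))
    target_corr <- m / tcrossprod(d)
    eg <- eigen(target_corr, symmetric = TRUE)
  }
  rt <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  withSeed(seed, {
    z <- matrix(stats::rnorm(nrow(target_corr) * T), nrow(target_corr), T)
    rt %*% z
  })
}

#' Stable names of the flattened structural feature vector
#'
#' Cortical block first (9 measures per region), then the noncortical block
#' (7 measures per region), so the flattening order is fixed by labels.
#' @param n_cortical,n_noncortical region counts.
#' @return character vector of `region.measure` ids.
#' @export
structuralFeatureIds <- function(n_cortical = 68L, n_noncortical = 115L) {
  cort_meas <- c("nvert", "area", "grayvol", "thickavg", "thicksd",
                 "meancurv", "gauscurv", "foldind", "curvind")
  sub_meas <- c("nvoxels", "volume", "normmean", "normsd", "normmin",
                "normmax", "normrange")
  c(if (n_cortical > 0L)
      as.vector(t(outer(sprintf("ctx%03d", seq_len(n_cortical)), cort_meas,
                        paste, sep = "."))),
    if (n_noncortical > 0L)
      as.vector(t(outer(sprintf("sub%03d", seq_len(n_noncortical)), sub_meas,
                        paste, sep = "."))))
}
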
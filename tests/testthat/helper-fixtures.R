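# Shared desk-scale fixtures, all generated in code.

# Small 20-site cohort: 16 ROIs (120 edges), 57 structural features.
tinyCohort <- function(seed = 7, d = 1.5, ...) {
  cfg <- generationConfig(n_rois = 16L, site_table = abideSiteTable(0.05),
                          n_informative_edges = 10L,
                          n_informative_struct = 5L,
                          n_cortical = 4L, n_noncortical = 3L,
                          effect_size_d = d, seed = seed, ...)
  generateCohort(cfg)
}

# Balanced 4-site cohort for mid-size recovery checks.
balancedSiteTable <- function(n_per_cell = 25L, n_sites = 4L) {
  data.frame(site = paste0("S", seq_len(n_sites)),
             n_autism = n_per_cell, n_td = n_per_cell,
             mean_age = 15, male_frac = 0.7)
}

# Separable two-class Gaussian feature data (first n_signal columns carry
# a standardized mean difference d); returns standardized splits.
separableData <- function(n = 400L, p = 20L, n_signal = 5L, d = 2,
                          seed = 1L) {
  set.seed(seed)
  y <- rep(c("autism", "td"), length.out = n)
  X <- matrix(rnorm(n * p), n, p)
  shift <- ifelse(y == "autism", d / 2, -d / 2)
  X[, seq_len(n_signal)] <- X[, seq_len(n_signal)] + shift
  colnames(X) <- sprintf("f%d", seq_len(p))
  idx <- sample(n)
  tr <- idx[seq_len(floor(0.5 * n))]
  va <- idx[(floor(0.5 * n) + 1L):floor(0.75 * n)]
  te <- idx[(floor(0.75 * n) + 1L):n]
  std <- fitStandardizer(X[tr, ])
  list(X = applyStandardizer(std, X), y = y, train = tr, val = va, test = te)
}

# Hand-rolled dense Chebyshev polynomial oracle: sum_k T_k(L) X W_k with
# the T_k matrices built explicitly.
chebDenseOracle <- function(X, lt, W) {
  K <- length(W)
  Tk <- list(diag(nrow(lt)))
  if (K >= 2) Tk[[2]] <- lt
  if (K >= 3) for (k in 3:K) Tk[[k]] <- 2 * lt %*% Tk[[k - 1]] - Tk[[k - 2]]
  Reduce(`+`, lapply(seq_len(K), function(k) Tk[[k]] %*% X %*% W[[k]]))
}

# An exactly-linear scorer dressed as an FCN: autism logit = x . w,
# td logit = 0 (relu pair trick), valid for every input.
linearFCN <- function(w) {
  p <- length(w)
  params <- list(W1 = cbind(w, -w), b1 = c(0, 0),
                 W2 = diag(2), b2 = c(0, 0),
                 W3 = rbind(c(0, 1), c(0, -1)), b3 = c(0, 0))
  fr <- rbind(min = rep(0, p), max = rep(1, p))
  methods::new("NetClassifier", architecture = "fcn",
               featureIds = sprintf("f%d", seq_len(p)), featureRange = fr,
               seed = 1L, params = params,
               spec = list(architecture = "fcn", hidden = c(2L, 2L),
                           dropout = 0),
               history = data.frame(), selectedIteration = 0L)
}
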
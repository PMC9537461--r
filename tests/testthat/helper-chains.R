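# Shared fixtures, all built in code.

# Deterministic chain: zero-variance clearances and a point-mass initial
# load, so every trajectory is the exact product composition.
make_deterministic_chain <- function(scs = c(10, 5), init = 100) {
  cqa <- quality_attribute("imp", "impurity", "ng/mg", ds_spec = 1)
  uos <- lapply(seq_along(scs), function(k) {
    unit_operation(k, paste0("UO", k),
                   models = list(imp = manufacturing_sc(log(scs[k]), 0,
                                                        cqa = cqa)))
  })
  process_chain(uos, list(cqa), ranges = list(imp = c(1L, length(scs))),
                init = list(imp = list(mean_log = log(init), sd_log = 0)))
}

# Well-controlled impurity process: large, low-variance clearances with a
# generous margin to the DS limit, so the conventional +/- 3 sd limits are
# tighter than the OOS-derived acceptance criteria at the early steps.
make_tight_control_chain <- function() {
  cqa <- quality_attribute("imp", "impurity", "ng/mg", ds_spec = 5.2,
                           fit_scale = "log")
  uos <- lapply(1:3, function(k) {
    unit_operation(k, paste0("UO", k),
                   models = list(imp = manufacturing_sc(2, 0.08, cqa = cqa)))
  })
  process_chain(uos, list(cqa), ranges = list(imp = c(1L, 3L)),
                init = list(imp = list(mean_log = log(1000), sd_log = 0.08)))
}

# 17-run face-centered central-composite dataset in coded units with a
# known generating model: log(SC) = 2 + 0.5 x1 + 0.3 x1 x2, noise sd 0.05.
make_ccf_truth_data <- function(seed) {
  corners <- as.matrix(expand.grid(x1 = c(-1, 1), x2 = c(-1, 1),
                                   x3 = c(-1, 1)))
  faces <- rbind(diag(3), -diag(3))
  colnames(faces) <- colnames(corners)
  centers <- matrix(0, 3, 3, dimnames = list(NULL, colnames(corners)))
  Z <- rbind(corners, faces, centers)
  set.seed(seed)
  mu <- 2 + 0.5 * Z[, "x1"] + 0.3 * Z[, "x1"] * Z[, "x2"]
  d <- as.data.frame(Z)
  d$y <- exp(mu + rnorm(nrow(Z), 0, 0.05))
  d
}

ccf_ranges <- list(x1 = c(-1, 1), x2 = c(-1, 1), x3 = c(-1, 1))
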
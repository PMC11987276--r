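# Shared slow fixtures, built once per test run.

# small cached phantom (moderate severity) reused across modules
phantom_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_phantom(severity_to_spec(3, phantom_spec(seed = 42)))
    cache
  }
})

# draw a plausible 10-column morphometric feature matrix for model-level tests
# (lognormal scales roughly matching phantom measurements)
synth_feature_matrix <- function(n, seed) {
  set.seed(seed)
  X <- cbind(
    max_diameter_3dd = exp(rnorm(n, log(6), 0.3)),
    mean_diameter_3dd = exp(rnorm(n, log(4), 0.3)),
    mean_sdc_tortuosity_3dd = exp(rnorm(n, log(5e-4), 0.5)),
    top1pct_curvature_3dd = exp(rnorm(n, log(0.1), 0.4)),
    vessel_density_3dd = exp(rnorm(n, log(0.05), 0.4)),
    max_diameter_whole = exp(rnorm(n, log(6), 0.3)),
    mean_diameter_whole = exp(rnorm(n, log(3.5), 0.3)),
    mean_sdc_tortuosity_whole = exp(rnorm(n, log(4e-4), 0.5)),
    top1pct_curvature_whole = exp(rnorm(n, log(0.08), 0.4)),
    vessel_density_whole = exp(rnorm(n, log(0.04), 0.4)))
  X
}


# 8-connected component count via flood fill (skeletons are 8-connected, so
# 4-connected labelling would overcount)
n_components8 <- function(mask) {
  m <- mask > 0
  lab <- matrix(0L, nrow(m), ncol(m))
  cur <- 0L
  idx <- which(m)
  H <- nrow(m)
  for (start in idx) {
    r0 <- (start - 1) %% H + 1; c0 <- (start - 1) %/% H + 1
    if (lab[r0, c0] > 0) next
    cur <- cur + 1L
    stack <- list(c(r0, c0)); lab[r0, c0] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nrow(m) && c >= 1 && c <= ncol(m) &&
            m[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          stack[[length(stack) + 1]] <- c(r, c)
        }
      }
    }
  }
  cur
}
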
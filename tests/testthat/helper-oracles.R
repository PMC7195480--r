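# Independent oracles and small fixture builders used across tests.
# These deliberately avoid the package's own code paths.

# Brute-force per-voxel flood fill (queue of single voxels, no
# vectorisation) -- independent connectivity oracle.
oracle_flood_fill <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  labels <- array(0L, dims)
  cur <- 0L
  for (lin in which(mask)) {
    if (labels[lin] > 0L) next
    cur <- cur + 1L
    queue <- list(arrayInd(lin, dims)[1, ])
    labels[lin] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        w <- v + offs[k, ]
        if (any(w < 1) || any(w > dims)) next
        if (mask[w[1], w[2], w[3]] && labels[w[1], w[2], w[3]] == 0L) {
          labels[w[1], w[2], w[3]] <- cur
          queue[[length(queue) + 1]] <- w
        }
      }
    }
  }
  labels
}

# Kruskal-Wallis H by explicit rank sums with tie correction.
oracle_kruskal_h <- function(values, groups) {
  g <- factor(groups)
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Small two-channel stack with hand-placed rectangular blobs; returns the
# stack plus the expected object masks.
toy_stack <- function(nz = 4, ny = 32, nx = 32, voxel = c(1, 1, 1)) {
  cfp <- array(0, c(nz, ny, nx))
  yfp <- array(0, c(nz, ny, nx))
  image_stack(list(CFP = cfp, YFP = yfp), voxel)
}

# Cohort simulator for mixed-model tests: volume-level responses with a
# mouse random intercept.
sim_lmm_cohort <- function(diff = 0.06, sd_mouse = 0.03, sd_resid = 0.05,
                           n_mice = c(11, 7), n_volumes = 10,
                           base = 0.67) {
  mk <- function(g, n, mu) {
    purrr::map_dfr(seq_len(n), function(m) {
      tibble::tibble(
        group = g,
        mouse_id = sprintf("%s%02d", g, m),
        value = mu + stats::rnorm(1, 0, sd_mouse) +
          stats::rnorm(n_volumes, 0, sd_resid)
      )
    })
  }
  dplyr::bind_rows(mk("a", n_mice[1], base), mk("b", n_mice[2], base + diff))
}
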
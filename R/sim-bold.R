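# Default rectangular geometry: brain = grid minus a 2-voxel x/y border;
# network and artifact masks are disjoint axis-aligned blocks inside it.
default_masks <- function(grid_shape) {
  gx <- grid_shape[1]; gy <- grid_shape[2]; gz <- grid_shape[3]
  brain <- array(FALSE, grid_shape)
  bx <- max(1, min(3, gx %/% 4)); by <- max(1, min(3, gy %/% 4))
  brain[bx:(gx - bx + 1), by:(gy - by + 1), ] <- TRUE
  block <- function(xr, yr) {
    m <- array(FALSE, grid_shape)
    m[xr, yr, ] <- m[xr, yr, ] | TRUE
    m & brain
  }
  qx <- max(2, gx %/% 4); qy <- max(2, gy %/% 4)
  network <- block(bx:(bx + qx), by:(by + qy))
  artifact <- block((gx - bx - qx + 1):(gx - bx + 1), (gy - by - qy + 1):(gy - by + 1))
  stopifnot(!any(network & artifact))
  list(brain = brain, network = network, artifact = artifact)
}

#' Generate a synthetic 4-D BOLD dataset
#'
#' Builds voxel time series as the sum of (i) an HRF-convolved gamma-power
#' envelope in "network" voxels (the neurally mediated component), (ii) an
#' RRF-convolved RVT series plus aliased cyclic-respiration sin/cos terms in
#' "artifact" voxels (the non-neural physiological component), and (iii)
#' white noise everywhere in the brain mask. In the isoelectric condition
#' the neural gain is zero while both respiration-derived terms keep their
#' configuration.
#'
#' Component series are standardised before scaling, so `beta_*` are effect
#' sizes relative to `noise_sd`.
#'
#' @param cfg A [sim_config()].
#' @param gamma_env Gamma amplitude envelope on the TR grid (numeric,
#'   length `n_volumes`).
#' @param rvt RVT series on the TR grid (numeric, length `n_volumes`).
#' @param resp_phase Respiratory phase at each volume time (radians).
#' @param masks Optional list with logical arrays `brain`, `network`,
#'   `artifact` (defaults to [sim_config()]-sized axis-aligned blocks).
#' @return A list with `bold` (a [bold_data()]) and `truth` (list: masks,
#'   the component series, `true_coupling_lag_s`, `condition`).
#' @export
gen_bold <- function(cfg, gamma_env, rvt, resp_phase, masks = NULL) {
  validate_sim_config(cfg)
  nt <- cfg$n_volumes
  stopifnot(length(gamma_env) == nt, length(rvt) == nt,
            length(resp_phase) == nt)
  if (is.null(masks)) masks <- default_masks(cfg$grid_shape)
  if (!identical(dim(masks$brain), as.integer(cfg$grid_shape))) {
    abort("gen_bold: mask dimensions must equal cfg$grid_shape")
  }
  stopifnot(all(masks$network <= masks$brain), all(masks$artifact <= masks$brain))

  zstd <- function(x) {
    s <- sd(x)
    if (s == 0) x * 0 else (x - mean(x)) / s
  }
  beta_n <- if (cfg$condition == "isoelectric") 0 else cfg$beta_neural
  neural <- zstd(hrf_convolve(gamma_env, tr_s = cfg$tr_s))
  slow_art <- zstd(rrf_convolve(rvt, tr_s = cfg$tr_s))
  cyclic <- (sin(resp_phase) + cos(resp_phase)) / sqrt(2)

  with_seed(cfg$seed + 2L, {
    nv <- prod(cfg$grid_shape)
    dat <- array(0, c(cfg$grid_shape, nt))
    mat <- matrix(0, nv, nt)
    if (cfg$noise_sd > 0) {
      bmask <- as.vector(masks$brain)
      mat[bmask, ] <- rnorm(sum(bmask) * nt, sd = cfg$noise_sd)
    }
    nmask <- as.vector(masks$network)
    amask <- as.vector(masks$artifact)
    if (any(nmask)) {
      mat[nmask, ] <- mat[nmask, ] + rep(beta_n * neural, each = sum(nmask))
    }
    if (any(amask)) {
      art_ts <- cfg$beta_artifact * slow_art + cfg$beta_cyclic * cyclic
      mat[amask, ] <- mat[amask, ] + rep(art_ts, each = sum(amask))
    }
    dat[] <- mat
    list(
      bold = bold_data(dat, tr_s = cfg$tr_s, mask = masks$brain),
      truth = list(
        network_mask = masks$network,
        artifact_mask = masks$artifact,
        neural_ts = neural, slow_artifact_ts = slow_art, cyclic_ts = cyclic,
        true_coupling_lag_s = cfg$coupling_lag_s,
        condition = cfg$condition
      )
    )
  })
}

#' Run every generator for one synthetic scan
#'
#' Convenience wrapper: respiration, LFP, and BOLD from one [sim_config()],
#' with all ground truth attached — the study-conditions entry point used by
#' the validation suite.
#'
#' @param cfg A [sim_config()].
#' @param n_channels Channels for [gen_lfp()].
#' @return A list with `cfg`, `resp` (the [gen_respiration()] output),
#'   `lfp` (the [gen_lfp()] output), `bold`, and `truth`.
#' @export
#' @examples
#' sim <- simulate_study(sim_config(n_volumes = 100, ephys_fs = 500, seed = 3))
#' sim$bold
simulate_study <- function(cfg, n_channels = 1) {
  resp_sim <- gen_respiration(cfg)
  lfp_sim <- gen_lfp(cfg, resp_sim, n_channels = n_channels)
  bold_sim <- gen_bold(cfg,
    gamma_env = lfp_sim$gamma_envelope$env,
    rvt = resp_sim$rvt_envelope$rvt,
    resp_phase = resp_sim$resp_phase$phase
  )
  list(cfg = cfg, resp = resp_sim, lfp = lfp_sim,
       bold = bold_sim$bold, truth = bold_sim$truth)
}
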
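#' Generate a synthetic cohort of larvae
#'
#' Draws per-fish latent kinematic parameters under the hierarchical model
#' latent = genotype level x clutch offset x fish offset (offsets additive on
#' the log scale for strictly positive parameters, additive on the natural
#' scale for bend angles), with the clutch offset shared by all fish of a
#' clutch regardless of genotype. The expectation of every latent across fish
#' equals the genotype-level calibrated value.
#'
#' @param config a [cohortConfig()].
#' @param n_fish optional named vector giving the total number of fish per
#'   genotype (distributed as evenly as possible across clutches); default is
#'   \code{n_clutches * fish_per_clutch_per_genotype} each.
#' @return data.frame with one row per fish: \code{fish_id}, \code{clutch},
#'   \code{genotype} and the latent parameter columns (\code{fwd_*},
#'   \code{trn_*}, \code{bout_rate}, \code{p_forward}, \code{esc_*}).
#' @examples
#' coh <- generateCohort(cohortConfig(seed = 7))
#' nrow(coh)  # 4 clutches x 15 fish x 2 genotypes = 120
#' @export
generateCohort <- function(config, n_fish = NULL) {
  stopifnot(inherits(config, "cohortConfig"))
  cal <- config$calibration
  set.seed(config$seed)
  gl <- config$genotype_labels
  nc <- config$n_clutches
  if (is.null(n_fish)) {
    n_fish <- rep(nc * config$fish_per_clutch_per_genotype, 2)
    names(n_fish) <- gl
  }
  if (is.null(names(n_fish))) names(n_fish) <- gl[seq_along(n_fish)]

  # genotype-level values, with the mutant effect scaled
  gval <- function(block, param, genotype) {
    v <- cal[[block]][[param]]
    if (genotype == gl[1]) v[["wt"]]
    else v[["wt"]] + config$effect_scale * (v[["mut"]] - v[["wt"]])
  }

  # log-scale SDs split into clutch and fish components
  split_sd <- function(cv) {
    tot <- sqrt(log(1 + cv^2)) * config$sd_scale
    sc <- config$clutch_frac * tot
    c(clutch = sc, fish = sqrt(pmax(tot^2 - sc^2, 0)))
  }

  pos_params <- list(
    fwd_distance = c("forward", "distance"), fwd_speed = c("forward", "speed"),
    fwd_bend = c("forward", "bend"), fwd_nosc = c("forward", "n_osc"),
    trn_distance = c("turn", "distance"), trn_speed = c("turn", "speed"),
    trn_bend = c("turn", "bend"), trn_nosc = c("turn", "n_osc"),
    bout_rate = c("session", "bout_rate"),
    esc_distance = c("escape", "distance"), esc_tbf = c("escape", "tbf"),
    esc_nosc = c("escape", "n_osc"), esc_latency = c("escape", "latency")
  )
  cv_of <- function(block, param) {
    if (block == "session") cal$session$rate_cv else cal[[block]]$fish_cv[[param]]
  }

  # clutch offsets (z-scores), one per clutch per parameter; distance/speed
  # pairs are drawn jointly with the block's fish-level correlation
  draw_pair <- function(n, rho) rbvnorm(n, 1, 1, rho)
  cl_z <- list()
  cl_z$fwd_ds <- draw_pair(nc, cal$forward$fish_rho_ds)
  cl_z$trn_ds <- draw_pair(nc, cal$turn$fish_rho_ds)
  singles <- setdiff(names(pos_params), c("fwd_distance", "fwd_speed",
                                          "trn_distance", "trn_speed"))
  for (p in singles) cl_z[[p]] <- stats::rnorm(nc)
  cl_z$esc_cbend <- stats::rnorm(nc)
  cl_z$esc_counter <- stats::rnorm(nc)

  rows <- list()
  fish_counter <- 0L
  for (g in names(n_fish)) {
    per_cl <- diff(round(seq(0, n_fish[[g]], length.out = nc + 1)))
    for (cl in seq_len(nc)) {
      nfish <- per_cl[cl]
      if (nfish == 0) next
      fz_fwd <- draw_pair(nfish, cal$forward$fish_rho_ds)
      fz_trn <- draw_pair(nfish, cal$turn$fish_rho_ds)
      fz <- lapply(stats::setNames(singles, singles),
                   function(p) stats::rnorm(nfish))
      fz_cb <- stats::rnorm(nfish)
      fz_ct <- stats::rnorm(nfish)
      df <- data.frame(
        fish_id = sprintf("f%03d", fish_counter + seq_len(nfish)),
        clutch = sprintf("c%d", cl),
        genotype = g,
        stringsAsFactors = FALSE
      )
      fish_counter <- fish_counter + nfish
      for (p in names(pos_params)) {
        blk <- pos_params[[p]][1]; par <- pos_params[[p]][2]
        sd2 <- split_sd(cv_of(blk, par))
        zc <- switch(p,
          fwd_distance = cl_z$fwd_ds[cl, 1], fwd_speed = cl_z$fwd_ds[cl, 2],
          trn_distance = cl_z$trn_ds[cl, 1], trn_speed = cl_z$trn_ds[cl, 2],
          cl_z[[p]][cl])
        zf <- switch(p,
          fwd_distance = fz_fwd[, 1], fwd_speed = fz_fwd[, 2],
          trn_distance = fz_trn[, 1], trn_speed = fz_trn[, 2],
          fz[[p]])
        df[[p]] <- gval(blk, par, g) *
          exp(zc * sd2["clutch"] + zf * sd2["fish"] -
              (sd2["clutch"]^2 + sd2["fish"]^2) / 2)
      }
      for (p in c("cbend", "counter")) {
        tot <- cal$escape$fish_sd[[p]] * config$sd_scale
        sc <- config$clutch_frac * tot
        sf <- sqrt(pmax(tot^2 - sc^2, 0))
        zc <- if (p == "cbend") cl_z$esc_cbend[cl] else cl_z$esc_counter[cl]
        zf <- if (p == "cbend") fz_cb else fz_ct
        df[[paste0("esc_", p)]] <- gval("escape", p, g) + zc * sc + zf * sf
      }
      df$p_forward <- gval("session", "p_forward", g)
      rows[[length(rows) + 1]] <- df
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
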
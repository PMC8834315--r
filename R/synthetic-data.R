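# Seeded synthetic-data generators with the statistical structure each
# pipeline stage assumes: filipin-like fields with perinuclear puncta,
# correlated channel pairs, lognormal densitometry tables, and docking
# score tables with a planted hit count.  Every generator is a pure
# function of its spec (seed included): regeneration is bit-identical,
# and each returns a ground-truth record sufficient to compute the
# expected downstream result without re-inspecting the data.

#' Specification of a synthetic filipin field
#'
#' Describes a stylized fluorescence micrograph: round cells of a
#' baseline cytoplasmic intensity on a dim background, with bright
#' puncta confined to a perinuclear annulus (0.3-0.6 of the cell
#' radius).  The accumulation parameter \code{a} in [0, 1] scales the
#' punctum count per cell from none (control-like) to
#' \code{max_puncta_per_cell} (fully storage-laden).  Intensities are on
#' an 8-bit-like scale; additive Gaussian noise is clamped at zero.
#'
#' @param width,height image size in pixels.
#' @param n_cells number of cells to place (non-overlapping).
#' @param cell_radius_range min/max cell radius in pixels.
#' @param accumulation a in [0, 1].
#' @param max_puncta_per_cell punctum count at a = 1.
#' @param punctum_intensity added intensity of a punctum.
#' @param punctum_radius punctum radius in pixels.
#' @param baseline cytoplasmic baseline intensity.
#' @param background off-cell background intensity.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed RNG seed; fixes the output exactly.
#' @return object of class \code{filipin_field_spec}.
#' @export
filipin_field_spec <- function(width = 256L, height = 256L, n_cells = 8L,
                               cell_radius_range = c(18, 30),
                               accumulation = 0.5,
                               max_puncta_per_cell = 15L,
                               punctum_intensity = 150,
                               punctum_radius = 2,
                               baseline = 40, background = 5,
                               noise_sd = 5, seed = 1L) {
  if (accumulation < 0 || accumulation > 1)
    abort_validation("'accumulation' must be in [0, 1]")
  if (any(c(punctum_intensity, baseline, background) < 0) || noise_sd < 0)
    abort_validation("intensities and noise SD must be >= 0")
  if (length(cell_radius_range) != 2L || any(cell_radius_range <= 0) ||
      cell_radius_range[1] > cell_radius_range[2])
    abort_validation("'cell_radius_range' must be increasing and positive")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_cells = as.integer(n_cells),
                 cell_radius_range = cell_radius_range,
                 accumulation = accumulation,
                 max_puncta_per_cell = as.integer(max_puncta_per_cell),
                 punctum_intensity = punctum_intensity,
                 punctum_radius = punctum_radius,
                 baseline = baseline, background = background,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "filipin_field_spec")
}

disk_pixels <- function(cx, cy, r, width, height) {
  x0 <- max(1L, floor(cx - r)); x1 <- min(width,  ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(height, ceiling(cy + r))
  xs <- x0:x1; ys <- y0:y1
  grid <- expand.grid(y = ys, x = xs)
  keep <- (grid$x - cx)^2 + (grid$y - cy)^2 <= r^2
  cbind(row = grid$y[keep], col = grid$x[keep])
}

#' Generate a synthetic filipin field with ground truth
#'
#' Places non-overlapping cells, fills each with the baseline
#' intensity, plants \code{round(a * max_puncta_per_cell)} puncta in
#' the perinuclear annulus of each cell, adds clamped Gaussian noise,
#' and returns both the image and a ground-truth record:
#' cell/punctum geometry, the noise-free supra-threshold intensity sum,
#' and recommended thresholds (halfway between background and baseline,
#' and halfway between baseline and the punctum peak).
#'
#' @param spec a \code{\link{filipin_field_spec}}.
#' @return list with \code{pixels} (intensity matrix) and \code{truth}
#'   (list: \code{cells}, \code{n_puncta}, \code{n_cell_pixels},
#'   \code{n_punctum_pixels}, \code{sum_punctum_intensity},
#'   \code{t_low}, \code{t_high}, \code{spec}).
#' @export
gen_filipin_field <- function(spec) {
  if (!inherits(spec, "filipin_field_spec"))
    abort_validation("'spec' must be a filipin_field_spec")
  with_seed(spec$seed, {
    w <- spec$width; h <- spec$height
    rmin <- spec$cell_radius_range[1]; rmax <- spec$cell_radius_range[2]
    cells <- data.frame(x = numeric(0), y = numeric(0), r = numeric(0))
    attempts <- 0L
    max_attempts <- 300L * spec$n_cells
    while (nrow(cells) < spec$n_cells) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        abort(sprintf("infeasible packing: placed %d of %d cells",
                      nrow(cells), spec$n_cells),
              "npcquant_generation_error")
      r <- stats::runif(1, rmin, rmax)
      x <- stats::runif(1, r + 1, w - r)
      y <- stats::runif(1, r + 1, h - r)
      if (nrow(cells) == 0L ||
          all(sqrt((cells$x - x)^2 + (cells$y - y)^2) > cells$r + r + 1)) {
        cells <- rbind(cells, data.frame(x = x, y = y, r = r))
      }
    }

    img <- matrix(spec$background, nrow = h, ncol = w)
    cell_mask <- matrix(FALSE, nrow = h, ncol = w)
    for (i in seq_len(nrow(cells))) {
      px <- disk_pixels(cells$x[i], cells$y[i], cells$r[i], w, h)
      img[px] <- spec$baseline
      cell_mask[px] <- TRUE
    }

    n_per_cell <- as.integer(round(spec$accumulation *
                                   spec$max_puncta_per_cell))
    punctum_mask <- matrix(FALSE, nrow = h, ncol = w)
    for (i in seq_len(nrow(cells))) {
      if (n_per_cell == 0L) next
      rad <- stats::runif(n_per_cell, 0.3, 0.6) * cells$r[i]
      ang <- stats::runif(n_per_cell, 0, 2 * pi)
      for (j in seq_len(n_per_cell)) {
        px <- disk_pixels(cells$x[i] + rad[j] * cos(ang[j]),
                          cells$y[i] + rad[j] * sin(ang[j]),
                          spec$punctum_radius, w, h)
        img[px] <- img[px] + spec$punctum_intensity
        punctum_mask[px] <- TRUE
      }
    }
    # overlapping puncta stack, so record the realised noise-free sums
    sum_punctum <- sum(img[punctum_mask])

    t_low <- (spec$background + spec$baseline) / 2
    t_high <- spec$baseline + spec$punctum_intensity / 2
    truth <- list(cells = cells, n_puncta = n_per_cell * nrow(cells),
                  n_cell_pixels = sum(cell_mask),
                  n_punctum_pixels = sum(punctum_mask),
                  sum_punctum_intensity = sum_punctum,
                  t_low = t_low, t_high = t_high, spec = spec)

    if (spec$noise_sd > 0)
      img <- pmax(img + matrix(stats::rnorm(h * w, 0, spec$noise_sd),
                               nrow = h), 0)
    list(pixels = img, truth = truth)
  })
}

#' Specification of a correlated two-channel pixel pair
#'
#' @param rho planted population correlation in [-1, 1].
#' @param n_pixels number of paired pixels.
#' @param mean,sd length-2 marginal mean and SD per channel.
#' @param seed RNG seed.
#' @return object of class \code{coloc_spec}.
#' @export
coloc_spec <- function(rho, n_pixels = 10000L, mean = c(1000, 1000),
                       sd = c(100, 100), seed = 1L) {
  if (abs(rho) > 1) abort_validation("'rho' must be in [-1, 1]")
  if (n_pixels < 2L)
    abort("'n_pixels' must be >= 2", "npcquant_generation_error")
  if (any(sd <= 0)) abort_validation("'sd' must be > 0")
  structure(list(rho = rho, n_pixels = as.integer(n_pixels),
                 mean = rep_len(mean, 2L), sd = rep_len(sd, 2L),
                 seed = as.integer(seed)),
            class = "coloc_spec")
}

#' Generate a channel pair with a planted correlation
#'
#' Shared-latent construction: with \eqn{\rho \ge 0},
#' \eqn{ch_i = \mu_i + \sigma_i(\sqrt{\rho}\,Z + \sqrt{1-\rho}\,E_i)}
#' for a common standard normal field \eqn{Z} and independent
#' \eqn{E_i}; for negative \eqn{\rho} the latent's sign is flipped in
#' channel 2.  The population correlation is exactly \eqn{\rho}.
#' Channels are clamped at zero (measure-zero event at the default
#' intensity scale) and shaped into square matrices when
#' \code{n_pixels} is a perfect square, else one row.
#'
#' @param spec a \code{\link{coloc_spec}}.
#' @return list with matrices \code{ch1}, \code{ch2} and the echoed
#'   \code{spec}.
#' @export
gen_coloc_pair <- function(spec) {
  if (!inherits(spec, "coloc_spec"))
    abort_validation("'spec' must be a coloc_spec")
  with_seed(spec$seed, {
    n <- spec$n_pixels
    rho <- abs(spec$rho)
    z <- stats::rnorm(n)
    e1 <- stats::rnorm(n); e2 <- stats::rnorm(n)
    latent1 <- sqrt(rho) * z + sqrt(1 - rho) * e1
    latent2 <- sqrt(rho) * z + sqrt(1 - rho) * e2
    if (spec$rho < 0) latent2 <- -latent2
    side <- sqrt(n)
    dims <- if (side == floor(side)) c(side, side) else c(1L, n)
    ch1 <- matrix(pmax(spec$mean[1] + spec$sd[1] * latent1, 0), nrow = dims[1])
    ch2 <- matrix(pmax(spec$mean[2] + spec$sd[2] * latent2, 0), nrow = dims[1])
    list(ch1 = ch1, ch2 = ch2, spec = spec)
  })
}

#' Specification of a synthetic densitometry experiment
#'
#' @param conditions character vector of condition labels; the first is
#'   the control unless \code{control} says otherwise.
#' @param fold_changes planted NPC1 fold change per condition vs the
#'   control (control must be 1).
#' @param f_R planted Endo H-resistant fraction per condition, in [0, 1].
#' @param n_lanes lanes (replicates) per condition.
#' @param cv lognormal coefficient of variation of the band noise.
#' @param control control condition label.
#' @param base_ratio control-condition NPC1/actin level.
#' @param actin_mean mean actin band signal (arbitrary units).
#' @param seed RNG seed.
#' @return object of class \code{blot_spec}.
#' @export
blot_spec <- function(conditions = c("DMSO", "treated"),
                      fold_changes = c(1, 2.5),
                      f_R = c(0.9, 0.9),
                      n_lanes = 4L, cv = 0.15, control = conditions[1],
                      base_ratio = 0.6, actin_mean = 1000, seed = 1L) {
  if (length(fold_changes) != length(conditions) ||
      length(f_R) != length(conditions))
    abort_validation("'fold_changes' and 'f_R' must match 'conditions'")
  if (any(fold_changes <= 0)) abort_validation("fold changes must be > 0")
  if (any(f_R < 0 | f_R > 1)) abort_validation("'f_R' must be in [0, 1]")
  if (!control %in% conditions)
    abort_validation("'control' must be one of 'conditions'")
  if (abs(fold_changes[match(control, conditions)] - 1) > 1e-12)
    abort_validation("the control condition's fold change must be 1")
  if (cv < 0) abort_validation("'cv' must be >= 0")
  structure(list(conditions = conditions, fold_changes = fold_changes,
                 f_R = f_R, n_lanes = as.integer(n_lanes), cv = cv,
                 control = control, base_ratio = base_ratio,
                 actin_mean = actin_mean, seed = as.integer(seed)),
            class = "blot_spec")
}

# mean-preserving lognormal multiplier: E[noise] = 1, CV = cv
lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Generate synthetic densitometry tables
#'
#' Per-lane NPC1/actin band signals with multiplicative
#' (mean-preserving) lognormal noise around the planted levels, and
#' matching Endo H glycoform bands around the planted resistant
#' fraction.  With \code{cv = 0} the recovered per-condition folds and
#' fractions equal the planted values exactly.
#'
#' @param spec a \code{\link{blot_spec}}.
#' @return list with \code{levels} (columns \code{lane_id},
#'   \code{condition}, \code{npc1_signal}, \code{actin_signal}),
#'   \code{glycoforms} (columns \code{lane_id}, \code{condition},
#'   \code{endoH_R}, \code{endoH_S}) and the echoed \code{spec}.
#' @export
gen_blot_dataset <- function(spec) {
  if (!inherits(spec, "blot_spec"))
    abort_validation("'spec' must be a blot_spec")
  with_seed(spec$seed, {
    rows <- lapply(seq_along(spec$conditions), function(i) {
      cond <- spec$conditions[i]
      nl <- spec$n_lanes
      actin <- spec$actin_mean * lognoise(nl, spec$cv)
      level <- spec$base_ratio * spec$fold_changes[i] * lognoise(nl, spec$cv)
      total_glyco <- spec$actin_mean * 0.5 * lognoise(nl, spec$cv)
      r_sig <- spec$f_R[i] * total_glyco * lognoise(nl, spec$cv)
      s_sig <- (1 - spec$f_R[i]) * total_glyco * lognoise(nl, spec$cv)
      lane_id <- sprintf("%s_%02d", cond, seq_len(nl))
      list(levels = data.frame(lane_id = lane_id, condition = cond,
                               npc1_signal = level * actin,
                               actin_signal = actin,
                               stringsAsFactors = FALSE),
           glyco = data.frame(lane_id = lane_id, condition = cond,
                              endoH_R = r_sig, endoH_S = s_sig,
                              stringsAsFactors = FALSE))
    })
    list(levels = do.call(rbind, lapply(rows, `[[`, "levels")),
         glycoforms = do.call(rbind, lapply(rows, `[[`, "glyco")),
         spec = spec)
  })
}

#' Specification of a synthetic docking score table
#'
#' @param n_compounds library size after filtration.
#' @param n_hits compounds planted at or below the reference energy.
#' @param reference_energy hit threshold in kcal/mol.
#' @param n_boundary how many of the hits sit exactly at the reference
#'   energy (boundary ties; must not exceed \code{n_hits}).
#' @param seed RNG seed.
#' @return object of class \code{screen_spec}.
#' @export
screen_spec <- function(n_compounds = 1920L, n_hits = 10L,
                        reference_energy = -11.3, n_boundary = 0L,
                        seed = 1L) {
  if (n_hits > n_compounds)
    abort_validation("'n_hits' must not exceed 'n_compounds'")
  if (n_boundary > n_hits)
    abort_validation("'n_boundary' must not exceed 'n_hits'")
  structure(list(n_compounds = as.integer(n_compounds),
                 n_hits = as.integer(n_hits),
                 reference_energy = reference_energy,
                 n_boundary = as.integer(n_boundary),
                 seed = as.integer(seed)),
            class = "screen_spec")
}

#' Generate a docking score table with a planted hit count
#'
#' Energies are drawn on the engine's printed 0.1 kcal/mol grid: hits
#' at or below the reference energy (with \code{n_boundary} of them
#' exactly on it), non-hits strictly above by at least 0.2 kcal/mol, so
#' \code{\link{select_hits}} at the spec's reference recovers exactly
#' the planted hit count.  Heavy-atom counts are drawn in 20-40, the
#' size range typical of screened drug-like molecules.
#'
#' @param spec a \code{\link{screen_spec}}.
#' @return compound table \code{data.frame} with a logical
#'   \code{is_planted_hit} ground-truth column.
#' @export
gen_screen_table <- function(spec) {
  if (!inherits(spec, "screen_spec"))
    abort_validation("'spec' must be a screen_spec")
  with_seed(spec$seed, {
    n <- spec$n_compounds; nh <- spec$n_hits
    ref <- spec$reference_energy
    e_hit <- ref - 0.1 * sample(0:25, nh, replace = TRUE)
    if (spec$n_boundary > 0L) e_hit[seq_len(spec$n_boundary)] <- ref
    e_non <- ref + 0.1 * sample(2:60, n - nh, replace = TRUE)
    energy <- c(e_hit, e_non)
    perm <- sample.int(n)
    df <- data.frame(
      compound_id = sprintf("SYN%05d", seq_len(n)),
      name = sprintf("synthetic compound %d", seq_len(n)),
      smiles = NA_character_,
      heavy_atoms = sample(20:40, n, replace = TRUE),
      binding_energy = round(energy[perm], 1),
      is_planted_hit = c(rep(TRUE, nh), rep(FALSE, n - nh))[perm],
      stringsAsFactors = FALSE)
    df$binding_efficiency <- ligand_efficiency(df$binding_energy,
                                               df$heavy_atoms)
    df$be_printed <- NA_character_
    df
  })
}
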
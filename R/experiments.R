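#' Configuration of a displacement-analysis run
#'
#' @param threshold_implant,threshold_cortex region-growing intensity
#'   thresholds (CT-like units; about 3500 for the implant and 1600 for the
#'   tibia cortex).
#' @param clip_fraction end-segment fraction for proximal/distal clipping.
#' @param side `"left"` or `"right"` leg (lateral sign of the local CS).
#' @param levelset_iterations level-set refinement steps (0 disables).
#' @param contour_max_points cap on double-contour points per object.
#' @param registration a `registration_control` list.
#' @param prealign use coarse principal-axis pre-alignment between scans.
#' @param cs_grid_spacing ray-grid spacing (mm) of the local-CS plateau
#'   projection; defaults to the voxel spacing scale.
#' @param seed_points optional list with `implant` and `cortex` world seed
#'   positions; defaults to the `seed_points` attribute that phantom
#'   volumes carry.
#' @export
experiment_config <- function(threshold_implant = 3500,
                              threshold_cortex = 1600,
                              clip_fraction = 0.20,
                              side = "right",
                              levelset_iterations = 10,
                              contour_max_points = 2000,
                              registration = registration_control(),
                              prealign = TRUE,
                              cs_grid_spacing = NULL,
                              seed_points = NULL) {
  list(threshold_implant = threshold_implant,
       threshold_cortex = threshold_cortex,
       clip_fraction = clip_fraction, side = side,
       levelset_iterations = levelset_iterations,
       contour_max_points = contour_max_points,
       registration = registration, prealign = prealign,
       cs_grid_spacing = cs_grid_spacing, seed_points = seed_points)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one-voxel 26-neighbourhood binary dilation
dilate26 <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
    sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
    sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
    tx <- max(1, 1 - dx):min(d[1], d[1] - dx)
    ty <- max(1, 1 - dy):min(d[2], d[2] - dy)
    tz <- max(1, 1 - dz):min(d[3], d[3] - dz)
    out[tx, ty, tz] <- out[tx, ty, tz] | mask[sx, sy, sz]
  }
  out
}

#' Segment the implant and tibia objects of a (valgus) scan
#'
#' Runs the segmentation stage: region growing (+ optional level-set
#' refinement) for implant and cortex, marching-cubes meshing, clipping of
#' the proximal/distal segments, double-contour construction for all four
#' objects, and the automatic implant local coordinate system. Implant
#' voxels (plus a one-voxel margin) are excluded from the cortex object so
#' that the tibia reference does not ride with the implant.
#'
#' @param volume the segmentation-image `ct_volume`.
#' @param config an `experiment_config`.
#' @return list with `implant_mesh`, `tibia_mesh`, `segments`, `contours`
#'   (implant / whole / proximal / distal), and `cs` (a `local_cs`).
#' @export
segment_objects <- function(volume, config = experiment_config()) {
  seeds <- config$seed_points %||% attr(volume, "seed_points")
  if (is.null(seeds))
    stop("no seed points: supply config$seed_points or use phantom volumes")
  imp_mask <- region_grow(volume, seeds$implant, config$threshold_implant)
  cor_mask <- region_grow(volume, seeds$cortex, config$threshold_cortex)
  if (config$levelset_iterations > 0) {
    imp_mask <- levelset_refine(volume, imp_mask,
                                iterations = config$levelset_iterations)
    cor_mask <- levelset_refine(volume, cor_mask,
                                iterations = config$levelset_iterations)
  }
  # exclude implant voxels (one-voxel margin) from the cortex object,
  # working only inside the implant bounding box
  bb <- mask_bbox(imp_mask, margin = 2)
  sub <- dilate26(imp_mask[bb[[1]], bb[[2]], bb[[3]], drop = FALSE])
  cm_sub <- cor_mask[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  cor_mask[bb[[1]], bb[[2]], bb[[3]]] <- cm_sub & !sub
  implant_mesh <- extract_mesh_volume(volume, imp_mask)
  tibia_mesh <- extract_mesh_volume(volume, cor_mask)
  segments <- clip_segments(tibia_mesh, fraction = config$clip_fraction,
                            implant_mesh = implant_mesh)
  cs <- build_local_cs(implant_mesh, side = config$side,
                       grid_spacing = config$cs_grid_spacing %||%
                         max(volume$spacing))
  mk <- function(mesh) build_double_contour(
    volume, mesh, max_points = config$contour_max_points)
  list(implant_mesh = implant_mesh, tibia_mesh = tibia_mesh,
       segments = segments, cs = cs,
       contours = list(implant = mk(implant_mesh),
                       whole = mk(segments$whole),
                       proximal = mk(segments$proximal),
                       distal = mk(segments$distal)))
}

# register the four objects of a segmented scan into a target image
register_objects <- function(seg, target, config, source_volume = NULL) {
  init <- if (isTRUE(config$prealign))
    coarse_prealign(seg$contours$whole, target, config$threshold_cortex,
                    source_volume = source_volume)
  else rigid_identity()
  regs <- lapply(seg$contours, function(ct)
    tryCatch(register(ct, target, init = init,
                      control = config$registration),
             error = function(e) e))
  list(registrations = regs, init = init)
}

# the three investigated object pairs: i vs j
object_pairs <- function() {
  list(`prox-vs-distal` = c("proximal", "distal"),
       `implant-vs-whole` = c("implant", "whole"),
       `implant-vs-prox` = c("implant", "proximal"))
}

# relative displacement of each pair, expressed in the local CS and
# decomposed; implant pairs get mTRE/MTPM over the implant mesh vertices
pair_results <- function(regs, seg) {
  lapply(names(object_pairs()), function(pn) {
    ij <- object_pairs()[[pn]]
    ri <- regs[[ij[1]]]; rj <- regs[[ij[2]]]
    if (inherits(ri, "error") || inherits(rj, "error"))
      return(structure(list(pair = pn, error = conditionMessage(
        if (inherits(ri, "error")) ri else rj)),
        class = "displacement_error"))
    M <- relative_displacement(ri$transform, rj$transform)
    is_implant <- ij[1] == "implant"
    decompose(to_local(M, seg$cs), pair = pn,
              points = if (is_implant) seg$implant_mesh$vertices,
              M_global = if (is_implant) M)
  }) |> stats::setNames(names(object_pairs()))
}

#' Analyse one valgus/varus scan pair
#'
#' The full measurement: segments implant and tibia in the valgus image,
#' clips the proximal/distal segments, builds double contours, registers
#' each object (implant, whole tibia, proximal, distal) into the varus
#' image, forms the relative displacements of the three investigated pairs
#' (proximal-vs-distal, implant-vs-whole-tibia, implant-vs-proximal-tibia),
#' expresses each in the implant local CS and decomposes it; implant pairs
#' additionally get mTRE and MTPM. A failure in one pair is recorded as a
#' `displacement_error` while the other pairs proceed.
#'
#' @param valgus,varus the two `ct_volume`s.
#' @param config an `experiment_config`.
#' @return list with `results` (three `displacement_result`s),
#'   `registrations`, `segmentation`, `init`.
#' @export
analyze_pair <- function(valgus, varus, config = experiment_config()) {
  seg <- segment_objects(valgus, config)
  ro <- register_objects(seg, varus, config, source_volume = valgus)
  list(results = pair_results(ro$registrations, seg),
       registrations = ro$registrations, segmentation = seg,
       init = ro$init)
}

#' Methodological-error experiment on repeat scans
#'
#' With `n` repeat scans of an unloaded specimen, every scan serves in turn
#' as the segmentation source and its objects are registered to each of the
#' remaining `n - 1` scans, yielding `n (n - 1)` apparent relative
#' displacements per object pair (90 for n = 10) with zero ground truth.
#' The mean apparent displacement is the accuracy of zero-displacement and
#' the standard deviation the precision, per parameter and per object pair;
#' the maximum absolute apparent displacement is reported as a conservative
#' error benchmark.
#'
#' @param scans list of `ct_volume`s (>= 2).
#' @param config an `experiment_config`.
#' @return an `error_summary`: `displacements` (one row per source/target/
#'   pair), `summary` (accuracy/precision/max_abs per parameter and pair),
#'   `n_scans`, `n_apparent`.
#' @export
methodological_error <- function(scans, config = experiment_config()) {
  n <- length(scans)
  if (n < 2) stop("need at least 2 repeat scans")
  rows <- list()
  for (s in seq_len(n)) {
    seg <- segment_objects(scans[[s]], config)
    for (t in seq_len(n)) {
      if (t == s) next
      ro <- register_objects(seg, scans[[t]], config,
                             source_volume = scans[[s]])
      res <- pair_results(ro$registrations, seg)
      for (pn in names(res)) {
        r <- res[[pn]]
        if (inherits(r, "displacement_error"))
          stop("registration failed (source ", s, " -> target ", t, ", ",
               pn, "): ", r$error)
        rows[[length(rows) + 1]] <-
          cbind(data.frame(source = s, target = t), as.data.frame(r))
      }
    }
  }
  disp <- do.call(rbind, rows)
  params <- c("dx", "dy", "dz", "dphix", "dphiy", "dphiz",
              "translation_magnitude", "rotation_magnitude", "mTRE", "MTPM")
  summ <- do.call(rbind, lapply(split(disp, disp$pair), function(d) {
    do.call(rbind, lapply(params, function(p) {
      v <- d[[p]]
      if (all(is.na(v))) return(NULL)
      data.frame(pair = d$pair[1], parameter = p,
                 accuracy = mean(v), precision = stats::sd(v),
                 max_abs = max(abs(v)), n = length(v))
    }))
  }))
  rownames(summ) <- NULL
  structure(list(displacements = disp, summary = summ, n_scans = n,
                 n_apparent = n * (n - 1)),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("<error_summary> %d scans, %d apparent displacements per pair\n",
              x$n_scans, x$n_apparent))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Tibia-deformation experiment
#'
#' Runs `analyze_pair` on each valgus/varus pair and summarises the
#' proximal-vs-distal relative displacement, which is attributed to tibia
#' deformation under the load. When the pairs carry phantom ground truth,
#' the imposed net bend is reported next to the recovered rotation
#' magnitude.
#'
#' @param pairs list of load pairs; each element has `valgus`, `varus` and
#'   optionally `truth` (as produced by `generate_load_pair`).
#' @param config an `experiment_config`.
#' @return list with `per_specimen` (data frame), `summary` (group means and
#'   SDs of the magnitudes), and `analyses`.
#' @export
deformation_experiment <- function(pairs, config = experiment_config()) {
  analyses <- lapply(pairs, function(p)
    analyze_pair(p$valgus, p$varus, config))
  per <- do.call(rbind, lapply(seq_along(analyses), function(i) {
    r <- analyses[[i]]$results[["prox-vs-distal"]]
    if (inherits(r, "displacement_error"))
      stop("specimen ", i, ": ", r$error)
    df <- cbind(data.frame(specimen = i), as.data.frame(r))
    tr <- pairs[[i]]$truth
    if (!is.null(tr)) {
      df$imposed_net_bend <- 2 * abs(tr$bend_angle)
      df$true_rotation <- rotation_angle(tr$true_M_prox_distal)
    }
    df
  }))
  list(per_specimen = per,
       summary = data.frame(
         translation_mean = mean(per$translation_magnitude),
         translation_sd = stats::sd(per$translation_magnitude),
         rotation_mean = mean(per$rotation_magnitude),
         rotation_sd = stats::sd(per$rotation_magnitude)),
       analyses = analyses)
}

#' Differentiation between fixed and loose implants
#'
#' Compares implant-displacement summaries (translation magnitude, rotation
#' magnitude, mTRE, MTPM) of fixed (cemented) and loose (uncemented) groups
#' for both tibia references (whole, proximal): group means/SDs, the number
#' of overlapping cases (loose values not exceeding the fixed maximum), the
#' paired Wilcoxon test of whole-vs-proximal within each group, and - when
#' an `error_summary` is supplied - the Mann-Whitney test of each group
#' against the methodological error.
#'
#' @param fixed,loose lists of `analyze_pair` outputs (paired by specimen,
#'   equal length).
#' @param error_summary optional `error_summary` from
#'   [methodological_error()].
#' @return data frame, one row per metric x reference.
#' @export
fixed_vs_loose_comparison <- function(fixed, loose, error_summary = NULL) {
  if (length(fixed) != length(loose))
    stop("fixed and loose result lists must be paired (equal length)")
  metrics <- c("translation_magnitude", "rotation_magnitude", "mTRE", "MTPM")
  refs <- c(whole = "implant-vs-whole", prox = "implant-vs-prox")
  pull <- function(analyses, ref, metric)
    vapply(analyses, function(a) {
      r <- a$results[[ref]]
      if (inherits(r, "displacement_error")) NA_real_ else r[[metric]]
    }, numeric(1))
  rows <- list()
  for (m in metrics) for (rn in names(refs)) {
    fv <- pull(fixed, refs[[rn]], m)
    lv <- pull(loose, refs[[rn]], m)
    # paired whole-vs-prox within each group
    fw <- pull(fixed, refs[["whole"]], m); fp <- pull(fixed, refs[["prox"]], m)
    lw <- pull(loose, refs[["whole"]], m); lp <- pull(loose, refs[["prox"]], m)
    err_p <- NA_real_
    if (!is.null(error_summary)) {
      ed <- error_summary$displacements
      ev <- ed[[m]][ed$pair == refs[[rn]]]
      if (!all(is.na(ev)))
        err_p <- mann_whitney_u(fv, ev, alternative = "greater")$p
    }
    rows[[length(rows) + 1]] <- data.frame(
      metric = m, reference = rn,
      fixed_mean = mean(fv), fixed_sd = stats::sd(fv),
      loose_mean = mean(lv), loose_sd = stats::sd(lv),
      overlap_cases = sum(lv <= max(fv)),
      p_whole_vs_prox_fixed = wilcoxon_signed_rank(fw - fp)$p,
      p_whole_vs_prox_loose = wilcoxon_signed_rank(lw - lp)$p,
      p_fixed_vs_error = err_p)
  }
  do.call(rbind, rows)
}

#' Mann-Whitney U test (exact for small samples)
#'
#' Rank-based comparison of two independent groups; exact p-values for
#' small tie-free samples, normal approximation with tie correction
#' otherwise. `U` counts the pairs `(a_i, b_j)` with `a_i > b_j` (plus half
#' the ties).
#'
#' @param a,b numeric vectors (n >= 3 each).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return list with `U` and `p`.
#' @export
mann_whitney_u <- function(a, b, alternative = "two.sided") {
  if (length(a) < 3 || length(b) < 3) stop("need n >= 3 per group")
  exact <- length(a) <= 25 && length(b) <= 25 &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                       correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Wilcoxon signed-rank test (exact for small samples)
#'
#' One-sample signed-rank test of paired differences against zero. Zero
#' differences are dropped (signed-rank convention); if all differences are
#' zero the result is the degenerate `p = 1`.
#'
#' @param d numeric vector of paired differences.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return list with `W` and `p`.
#' @export
wilcoxon_signed_rank <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  if (length(d) == 0) return(list(W = 0, p = 1))
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    stats::wilcox.test(d, alternative = alternative, exact = exact,
                       correct = TRUE))
  list(W = unname(wt$statistic), p = wt$p.value)
}

#' Exact sign test for paired comparisons
#'
#' Binomial test of the number of pairs with `x > y` against one half.
#'
#' @param x,y paired numeric vectors.
#' @param alternative passed to [stats::binom.test()].
#' @return list with `successes`, `n` and `p`.
#' @export
sign_test <- function(x, y, alternative = "greater") {
  stopifnot(length(x) == length(y))
  ok <- x != y
  k <- sum(x[ok] > y[ok])
  bt <- stats::binom.test(k, sum(ok), 0.5, alternative = alternative)
  list(successes = k, n = sum(ok), p = bt$p.value)
}

#' Tabulate displacement results of several analyses
#'
#' @param analyses list of `analyze_pair` outputs.
#' @return data frame with one row per specimen x object pair.
#' @export
displacement_table <- function(analyses) {
  do.call(rbind, lapply(seq_along(analyses), function(i) {
    do.call(rbind, lapply(analyses[[i]]$results, function(r) {
      if (inherits(r, "displacement_error")) return(NULL)
      cbind(data.frame(specimen = i), as.data.frame(r))
    }))
  }))
}
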
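## Per-SNP cluster geometry and the polar allele-frequency transform.
##
## A SNP's genotype classes (AA, AB, BB) form three bivariate clusters in
## (A-probe, B-probe) intensity space.  Lines through the two homozygous
## centroids, angled at each cluster's own orientation, intersect at an
## origin O; a pooled hybridization signal is expressed in the oblique
## coordinate frame spanned by the AA and BB directions from O, its angle
## (after a heterozygote-calibrated normalization factor NF) interpolated
## linearly to an allele frequency with AA -> 1, AB -> 0.5, BB -> 0.

DEG <- 180 / pi

## Orientation of a Gaussian cluster's major axis (degrees), vectorised.
## theta = 0.5 * atan2(2 Cxy, Cxx - Cyy), the canonical major-axis angle.
## Isotropic covariance has no defined orientation; callers supply a
## per-class fallback (AA along x, BB along y, AB at 45 degrees).
.cluster_angle <- function(cxx, cxy, cyy, fallback = 0) {
  iso <- abs(cxy) < .Machine$double.eps^0.5 &
    abs(cxx - cyy) < .Machine$double.eps^0.5
  th <- 0.5 * atan2(2 * cxy, cxx - cyy) * DEG
  th <- th %% 180
  th[iso] <- fallback
  th
}

#' Orientation angle of an intensity cluster
#'
#' Returns the orientation of the major axis of a bivariate genotype
#' cluster with respect to the horizontal (A-probe) axis, in degrees.
#' This is the "degree of rotation" used to anchor the lines through the
#' homozygous cluster centroids when locating the origin of the polar
#' allele-frequency transform.
#'
#' @param covariance A 2x2 covariance matrix (intensity squared units).
#' @param fallback Angle (degrees) returned for an isotropic covariance,
#'   whose orientation is undefined; SNPs hitting this case should be
#'   flagged low-confidence by the caller.
#' @return Angle in degrees, in `[0, 180)`; ordinary intensity clusters
#'   fall in `[0, 90]`.
#' @examples
#' cluster_angle(matrix(c(4, 0, 0, 1), 2))   # 0: x-dominant
#' cluster_angle(matrix(c(2, 1, 1, 2), 2))   # 45
#' cluster_angle(matrix(c(1, 0, 0, 4), 2))   # 90: y-dominant
#' @export
cluster_angle <- function(covariance, fallback = 0) {
  stopifnot(is.matrix(covariance), all(dim(covariance) == 2))
  if (covariance[1, 1] < 0 || covariance[2, 2] < 0)
    stop("negative variance in covariance matrix")
  if (abs(covariance[1, 2] - covariance[2, 1]) > 1e-8)
    stop("covariance matrix must be symmetric")
  det2 <- covariance[1, 1] * covariance[2, 2] - covariance[1, 2]^2
  if (det2 < -1e-8) stop("covariance matrix is not positive semidefinite")
  .cluster_angle(covariance[1, 1], covariance[1, 2], covariance[2, 2],
                 fallback = fallback)
}

## Intersection of the line through point a at angle_a with the line
## through point b at angle_b (angles in degrees).  Vectorised; returns
## NA coordinates where the lines are closer to parallel than tol degrees.
.line_intersection <- function(ax, ay, angle_a, bx, by, angle_b,
                               tol = 0.5) {
  ra <- angle_a / DEG
  rb <- angle_b / DEG
  cross <- sin(ra - rb)          # d_a x d_b for unit direction vectors
  bad <- abs(cross) < sin(tol / DEG)
  ## solve a + t*d_a = b + s*d_b  =>  t = (b - a) x d_b / (d_a x d_b)
  t <- ((bx - ax) * sin(rb) - (by - ay) * cos(rb)) / -cross
  ox <- ax + t * cos(ra)
  oy <- ay + t * sin(ra)
  ox[bad] <- NA_real_
  oy[bad] <- NA_real_
  list(x = ox, y = oy, parallel = bad)
}

#' Origin of the polar allele-frequency transform
#'
#' Computes the origin O as the intersection of the line through the AA
#' centroid at angle `theta_aa` with the line through the BB centroid at
#' angle `theta_bb`, and the (generally oblique) axis directions from O
#' toward each homozygous centroid.
#'
#' @param aa_centroid,bb_centroid Numeric length-2 centroids (x, y).
#' @param theta_aa,theta_bb Cluster orientation angles in degrees.
#' @param tol Minimum angular separation (degrees) below which the lines
#'   are treated as parallel and the SNP is unusable.
#' @return A list with `origin` (length-2 numeric), `x_axis` (unit vector
#'   toward the AA centroid) and `y_axis` (unit vector toward the BB
#'   centroid).
#' @examples
#' compute_origin(c(10, 1), 0, c(1, 10), 90)$origin  # c(1, 1)
#' @export
compute_origin <- function(aa_centroid, theta_aa, bb_centroid, theta_bb,
                           tol = 0.5) {
  o <- .line_intersection(aa_centroid[1], aa_centroid[2], theta_aa,
                          bb_centroid[1], bb_centroid[2], theta_bb,
                          tol = tol)
  if (o$parallel)
    stop("homozygous cluster lines are (near-)parallel; origin undefined")
  origin <- c(o$x, o$y)
  u <- aa_centroid - origin
  v <- bb_centroid - origin
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("a homozygous centroid coincides with the origin")
  list(origin = origin, x_axis = u / nu, y_axis = v / nv)
}

## Oblique coordinates of points relative to origin and axis directions.
## Solves p - O = xp * u + yp * v, vectorised over rows.
.oblique_coords <- function(px, py, ox, oy, ux, uy, vx, vy) {
  det <- ux * vy - uy * vx
  dx <- px - ox
  dy <- py - oy
  list(x = (dx * vy - dy * vx) / det,
       y = (ux * dy - uy * dx) / det)
}

#' Normalization factor for differential allelic intensity
#'
#' The heterozygote cluster of a perfectly behaved SNP sits symmetrically
#' between the AA and BB directions; real probes differ in brightness, so
#' the AB centroid is pulled toward one axis.  NF rescales the y' (BB-axis)
#' coordinate so that the corrected angle of the AB centroid is exactly 45
#' degrees, i.e. the heterozygote maps to allele frequency 0.5 (a form of
#' k-correction).
#'
#' @param x_ab,y_ab Oblique coordinates of the AB centroid relative to the
#'   origin (see [compute_origin()]).
#' @return The scalar NF = x'_AB / y'_AB.
#' @export
normalization_factor <- function(x_ab, y_ab) {
  if (!is.finite(x_ab) || !is.finite(y_ab) || x_ab <= 0 || y_ab <= 0)
    stop("AB centroid must lie strictly inside the quadrant spanned by ",
         "the AA and BB directions (collapsed heterozygote cluster?)")
  x_ab / y_ab
}

## NF-corrected angle (degrees) and AF for oblique coordinates; vectorised.
## AF = 1 - phi/90 pins AA (phi = 0) to 1, AB (phi = 45 by construction of
## NF) to 0.5 and BB (phi = 90) to 0.  Values outside [0, 1] are retained.
.af_from_oblique <- function(xp, yp, nf) {
  at_origin <- abs(xp) < 1e-9 & abs(yp) < 1e-9
  phi <- atan2(nf * yp, xp) * DEG
  af <- 1 - phi / 90
  af[at_origin] <- NA_real_
  af
}

## Inverse of .af_from_oblique for the simulator: oblique *direction*
## (not yet scaled) whose corrected angle corresponds to allele frequency af.
.oblique_direction_for_af <- function(af, nf) {
  phi <- (1 - af) * 90 / DEG
  list(x = cos(phi), y = sin(phi) / nf)
}

#' Derive polar-transform geometry for a table of cluster models
#'
#' Computes, per SNP, the cluster orientation angles, the origin O, the
#' oblique axis directions, the normalization factor NF and the radii of
#' the three centroids from O.  SNPs whose geometry is degenerate
#' (near-parallel homozygous lines, collapsed heterozygote cluster,
#' isotropic homozygous covariance) are flagged rather than dropped.
#'
#' @param clusters A cluster-model data frame with one row per SNP and
#'   columns `snp_id`, then for each class `aa`, `ab`, `bb`: `<class>_x`,
#'   `<class>_y`, `<class>_cxx`, `<class>_cxy`, `<class>_cyy`.
#' @param angle_tol Minimum separation (degrees) of the homozygous-line
#'   angles before a SNP is flagged as parallel.
#' @return A data frame with one row per SNP: `snp_id`, `theta_aa`,
#'   `theta_ab`, `theta_bb`, `o_x`, `o_y`, axis direction columns `ux`,
#'   `uy`, `vx`, `vy`, `nf`, centroid radii `r_aa`, `r_ab`, `r_bb`, and
#'   logical `flagged` with a `flag_reason` string.
#' @export
derive_cluster_geometry <- function(clusters, angle_tol = 0.5) {
  stopifnot(is.data.frame(clusters), "snp_id" %in% names(clusters))
  n <- nrow(clusters)
  th_aa <- .cluster_angle(clusters$aa_cxx, clusters$aa_cxy,
                          clusters$aa_cyy, fallback = 0)
  th_ab <- .cluster_angle(clusters$ab_cxx, clusters$ab_cxy,
                          clusters$ab_cyy, fallback = 45)
  th_bb <- .cluster_angle(clusters$bb_cxx, clusters$bb_cxy,
                          clusters$bb_cyy, fallback = 90)
  iso_hom <- (abs(clusters$aa_cxy) < 1e-12 &
                abs(clusters$aa_cxx - clusters$aa_cyy) < 1e-12) |
    (abs(clusters$bb_cxy) < 1e-12 &
       abs(clusters$bb_cxx - clusters$bb_cyy) < 1e-12)

  o <- .line_intersection(clusters$aa_x, clusters$aa_y, th_aa,
                          clusters$bb_x, clusters$bb_y, th_bb,
                          tol = angle_tol)
  ux <- clusters$aa_x - o$x; uy <- clusters$aa_y - o$y
  vx <- clusters$bb_x - o$x; vy <- clusters$bb_y - o$y
  nu <- sqrt(ux^2 + uy^2); nv <- sqrt(vx^2 + vy^2)
  ux <- ux / nu; uy <- uy / nu
  vx <- vx / nv; vy <- vy / nv

  ab <- .oblique_coords(clusters$ab_x, clusters$ab_y, o$x, o$y,
                        ux, uy, vx, vy)
  collapsed <- !is.na(ab$x) & (ab$x <= 1e-9 | ab$y <= 1e-9)
  nf <- ab$x / ab$y
  nf[collapsed] <- NA_real_

  r_ab0 <- sqrt((clusters$ab_x - o$x)^2 + (clusters$ab_y - o$y)^2)

  flagged <- o$parallel | collapsed | iso_hom | !is.finite(nf)
  reason <- rep("", n)
  reason[iso_hom] <- "isotropic-homozygous-cluster"
  reason[collapsed] <- "collapsed-heterozygote"
  reason[o$parallel] <- "parallel-homozygous-lines"

  data.frame(snp_id = clusters$snp_id,
             theta_aa = th_aa, theta_ab = th_ab, theta_bb = th_bb,
             o_x = o$x, o_y = o$y,
             ux = ux, uy = uy, vx = vx, vy = vy,
             nf = nf,
             r_aa = nu, r_ab = r_ab0, r_bb = nv,
             flagged = flagged, flag_reason = reason,
             stringsAsFactors = FALSE)
}

#' Allele-frequency estimate for a single replicate intensity point
#'
#' Transforms an intensity point into the oblique frame of a SNP's cluster
#' geometry, computes its NF-corrected angle, and converts the angle to an
#' allele frequency for allele A by linear interpolation between the AA
#' direction (AF 1) and the BB direction (AF 0), with the AB centroid
#' pinned to AF 0.5.  Estimates slightly outside `[0, 1]` are retained for
#' downstream diagnostics rather than clipped.
#'
#' @param point Numeric length-2 intensity point (x, y).
#' @param geometry A single-row geometry record as produced by
#'   [derive_cluster_geometry()] (or a list with the same fields).
#' @return The allele-frequency estimate; `NA` (flagged) if the point
#'   coincides with the origin.
#' @export
estimate_replicate_af <- function(point, geometry) {
  ob <- .oblique_coords(point[1], point[2], geometry$o_x, geometry$o_y,
                        geometry$ux, geometry$uy, geometry$vx, geometry$vy)
  .af_from_oblique(ob$x, ob$y, geometry$nf)
}

#' Average replicate allele-frequency estimates for one pool
#'
#' @param replicate_afs Numeric vector of per-replicate AF estimates.
#' @return List with `af` (mean), `se` (standard error of the mean; `NA`
#'   with a single replicate, in which case `flagged` is `TRUE`) and
#'   `n_replicates`.
#' @export
aggregate_replicates <- function(replicate_afs) {
  replicate_afs <- replicate_afs[!is.na(replicate_afs)]
  n <- length(replicate_afs)
  if (n == 0) stop("no replicate AF estimates to aggregate")
  se <- if (n >= 2) stats::sd(replicate_afs) / sqrt(n) else NA_real_
  list(af = mean(replicate_afs), se = se, n_replicates = n,
       flagged = n < 2)
}

## Radius of the expected *individual-sample* signal at allele frequency af:
## linear interpolation of the centroid radii (BB at 0, AB at 0.5, AA at 1),
## with af clamped into [0, 1] for the interpolation.
.expected_radius <- function(af, r_aa, r_ab, r_bb) {
  a <- pmin(pmax(af, 0), 1)
  ifelse(a >= 0.5,
         r_ab + (a - 0.5) / 0.5 * (r_aa - r_ab),
         r_bb + a / 0.5 * (r_ab - r_bb))
}

#' Estimate pooled allele frequencies from replicate intensities
#'
#' The workhorse of the intensity stage: joins replicate intensity points
#' to per-SNP cluster geometry, computes each replicate's polar-transform
#' AF estimate and its r/r' intensity-radius ratio (observed radius from
#' the origin over the radius expected for an average individual sample at
#' the same allele frequency), then averages replicates within each pool.
#'
#' @param clusters Cluster-model data frame (see
#'   [derive_cluster_geometry()]), or a pre-computed geometry data frame
#'   passed via `geometry`.
#' @param replicates Data frame of replicate intensities with columns
#'   `snp_id`, `pool_id`, `replicate_id`, `x`, `y`.
#' @param geometry Optional pre-computed geometry (skips re-derivation).
#' @return A list of class `pool_af` with elements
#'   \describe{
#'     \item{pools}{per SNP x pool: `snp_id`, `pool_id`, `af`, `se`,
#'       `n_replicates`, `flagged`.}
#'     \item{replicates}{per replicate: `snp_id`, `pool_id`,
#'       `replicate_id`, `af`, `r_ratio`.}
#'     \item{geometry}{the per-SNP geometry used, including flags.}
#'   }
#' @export
estimate_pool_af <- function(clusters, replicates, geometry = NULL) {
  if (is.null(geometry)) geometry <- derive_cluster_geometry(clusters)
  stopifnot(all(c("snp_id", "pool_id", "replicate_id", "x", "y") %in%
                  names(replicates)))
  idx <- match(replicates$snp_id, geometry$snp_id)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " replicate rows reference SNPs without a ",
            "cluster model; skipped")
    replicates <- replicates[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  g <- geometry[idx, , drop = FALSE]
  ob <- .oblique_coords(replicates$x, replicates$y, g$o_x, g$o_y,
                        g$ux, g$uy, g$vx, g$vy)
  af <- .af_from_oblique(ob$x, ob$y, g$nf)
  af[g$flagged] <- NA_real_
  r <- sqrt((replicates$x - g$o_x)^2 + (replicates$y - g$o_y)^2)
  r_exp <- .expected_radius(af, g$r_aa, g$r_ab, g$r_bb)
  r_ratio <- r / r_exp

  rep_out <- data.frame(snp_id = replicates$snp_id,
                        pool_id = replicates$pool_id,
                        replicate_id = replicates$replicate_id,
                        af = af, r_ratio = r_ratio,
                        stringsAsFactors = FALSE)

  key <- paste(rep_out$snp_id, rep_out$pool_id, sep = "\t")
  ok <- !is.na(af)
  af0 <- ifelse(ok, af, 0)
  s1 <- rowsum(af0, key)            # rows sorted by key
  s2 <- rowsum(af0^2, key)
  n_rep <- rowsum(as.numeric(ok), key)
  mean_af <- ifelse(n_rep > 0, s1 / n_rep, NA_real_)
  ss <- pmax(s2 - n_rep * mean_af^2, 0)
  se <- ifelse(n_rep >= 2, sqrt(ss / (n_rep - 1) / n_rep), NA_real_)
  rn <- rownames(s1)
  pools <- data.frame(snp_id = sub("\t.*$", "", rn),
                      pool_id = sub("^.*\t", "", rn),
                      af = as.vector(mean_af), se = as.vector(se),
                      n_replicates = as.integer(n_rep),
                      stringsAsFactors = FALSE)
  pools$flagged <- pools$n_replicates < 2 | !is.finite(pools$af)
  rownames(pools) <- NULL

  structure(list(pools = pools, replicates = rep_out, geometry = geometry),
            class = "pool_af")
}

#' @export
print.pool_af <- function(x, ...) {
  cat("Pooled allele-frequency estimates\n")
  cat("  SNPs:  ", length(unique(x$pools$snp_id)), "\n")
  cat("  pools: ", length(unique(x$pools$pool_id)), "\n")
  cat("  flagged SNP x pool combinations: ", sum(x$pools$flagged), "\n")
  invisible(x)
}
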
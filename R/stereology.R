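# Grid construction and the unbiased stereological estimators: V_V by point
# counting, S_V by intersection counting, Q_A with a Gundersen unbiased
# counting frame, absolute volumes, and precision accounting (CE, OCV/OCE).

#' Build an M36 test grid
#'
#' A 6 x 6 point lattice with unit length `d`: 36 points, each carrying a
#' test segment of length `0.5 d` (total test line `18 d`), nominal test
#' area `36.36 d^2` (area per point `1.01 d^2`), and an unbiased counting
#' frame of area `a_frame <= 36.36 d^2` (default `(5d)^2`) whose top and
#' left edges are inclusion edges and whose bottom and right edges, with
#' their infinite extensions, are forbidden. The grid carries a uniform
#' random translation within one grid period (and an optional random
#' rotation, off by default: sections produced by an IUR design do not
#' require isotropic line orientation).
#'
#' @param d Grid unit length, micrometres.
#' @param seed Integer seed for the random placement.
#' @param frame_side Counting-frame side length (micrometres), default `6 d`.
#' @param rotate Logical; also draw a random grid rotation (stored, applied
#'   by [count_field()] to the test segments).
#' @return Object of class `grid_spec`.
#' @export
build_grid <- function(d, seed, frame_side = 5 * d, rotate = FALSE) {
  stopifnot(d > 0, frame_side > 0)
  if (frame_side^2 > 36.36 * d^2) {
    stop("counting frame area must not exceed the test area 36.36 d^2")
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  structure(list(
    d = d, n_points = 36L,
    seg_len = 0.5 * d,
    total_test_line = 18 * d,
    test_area = 36.36 * d^2,
    area_per_point = 1.01 * d^2,
    frame_side = frame_side,
    a_frame = frame_side^2,
    offset = stats::runif(2, 0, d),       # lattice translation, one period
    frame_u = stats::runif(2),            # frame position, unit square
    angle = if (rotate) stats::runif(1, 0, pi) else 0,
    seed = seed
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> M36, d = %g um: 36 points, test line %g um, test area %g um^2, frame %g x %g um\n",
              x$d, x$total_test_line, x$test_area, x$frame_side, x$frame_side))
  invisible(x)
}

#' Count a field with a test grid
#'
#' Exact-geometry counting on a synthetic field: grid points are classified
#' by point-in-circle tests (lumen, epithelium, interstitium, plus overlaid
#' cell classes), test segments are intersected with tubule outer circles
#' (transversal crossings; tangencies count once), and cell profiles are
#' accepted by the unbiased counting-frame rule (profiles intersecting the
#' frame are counted unless they touch the forbidden bottom/right edges or
#' their extensions). All probes are placed toroidally: the point lattice and
#' segments wrap at the field boundary, and the frame is dropped uniformly
#' over the full field period with the profiles tested against their
#' periodic copies, which makes every probe exactly uniform over the field.
#' Exact coverage of the point lattice additionally requires the lattice to
#' tile the field, i.e. `6 d` should equal the field side (the cohort
#' defaults use `d = field / 6`).
#'
#' @param geom A [generate_geometry()] field.
#' @param grid A [build_grid()] grid; the frame must fit inside one field
#'   period.
#' @param luminal_surface Logical; also count intersections with the luminal
#'   (inner) tubule boundary.
#' @return Object of class `count_record`: named point counts `P`
#'   (`epithelium`, `lumen`, `interstitium`), total `SP`, overlaid cell point
#'   counts `P_cell`, intersection count `I` (and `I_luminal` if requested),
#'   frame-accepted counts `Q` per class, `a_frame` (um^2) and the line
#'   length `L` (um).
#' @export
count_field <- function(geom, grid, luminal_surface = FALSE) {
  stopifnot(inherits(geom, "tissue_geometry"), inherits(grid, "grid_spec"))
  W <- geom$width; H <- geom$height
  if (grid$frame_side > W || grid$frame_side > H) {
    stop("counting frame does not fit inside the field")
  }
  d <- grid$d
  ij <- expand.grid(i = 0:5, j = 0:5)
  px <- (grid$offset[1] + ij$i * d) %% W
  py <- (grid$offset[2] + ij$j * d) %% H

  tub <- geom$tubules
  classify <- function(x, y) {
    if (nrow(tub) == 0) return("interstitium")
    d2 <- (tub$x - x)^2 + (tub$y - y)^2
    if (any(d2 < tub$lumen_r^2)) return("lumen")
    if (any(d2 < tub$outer_r^2)) return("epithelium")
    "interstitium"
  }
  cls <- vapply(seq_along(px), function(k) classify(px[k], py[k]), "")
  P <- c(epithelium = sum(cls == "epithelium"),
         lumen = sum(cls == "lumen"),
         interstitium = sum(cls == "interstitium"))

  cells <- geom$cells
  P_cell <- c(leydig = 0L, sertoli = 0L, germ = 0L)
  if (nrow(cells)) {
    for (cl in names(P_cell)) {
      sub <- cells[cells$class == cl, , drop = FALSE]
      if (nrow(sub) == 0) next
      hit <- vapply(seq_along(px), function(k) {
        any((sub$x - px[k])^2 + (sub$y - py[k])^2 < sub$r^2)
      }, logical(1))
      P_cell[[cl]] <- sum(hit)
    }
  }

  # test segments: length 0.5 d from each point, direction = grid angle,
  # wrapped toroidally in x/y
  # split a segment at field boundaries and wrap the remainder (toroidal)
  seg_pieces <- function(x0, y0, dx, dy) {
    x1 <- x0 + dx; y1 <- y0 + dy
    ts <- numeric(0)
    if (dx > 0 && x1 > W) ts <- c(ts, (W - x0) / dx)
    if (dx < 0 && x1 < 0) ts <- c(ts, (0 - x0) / dx)
    if (dy > 0 && y1 > H) ts <- c(ts, (H - y0) / dy)
    if (dy < 0 && y1 < 0) ts <- c(ts, (0 - y0) / dy)
    if (!length(ts)) return(list(c(x0, y0, x1, y1)))
    t0 <- min(ts)
    mx <- x0 + t0 * dx; my <- y0 + t0 * dy
    eps <- 1e-9
    nx <- mx; ny <- my
    if (dx > 0 && abs(mx - W) < eps) nx <- 0
    if (dx < 0 && abs(mx) < eps) nx <- W
    if (dy > 0 && abs(my - H) < eps) ny <- 0
    if (dy < 0 && abs(my) < eps) ny <- H
    c(list(c(x0, y0, mx, my)),
      seg_pieces(nx, ny, dx * (1 - t0), dy * (1 - t0)))
  }
  I <- 0L; I_lum <- 0L
  if (nrow(tub)) {
    for (k in seq_along(px)) {
      pieces <- seg_pieces(px[k], py[k],
                           cos(grid$angle) * grid$seg_len,
                           sin(grid$angle) * grid$seg_len)
      for (p in pieces) {
        for (ti in seq_len(nrow(tub))) {
          I <- I + segment_circle_intersections(p[1], p[2], p[3], p[4],
                                                tub$x[ti], tub$y[ti],
                                                tub$outer_r[ti])
          if (luminal_surface && tub$lumen_r[ti] > 0) {
            I_lum <- I_lum + segment_circle_intersections(
              p[1], p[2], p[3], p[4], tub$x[ti], tub$y[ti], tub$lumen_r[ti])
          }
        }
      }
    }
  }

  # unbiased counting frame, toroidal placement: the frame is dropped
  # uniformly over the full field period and the cells are tested together
  # with their 3 x 3 periodic copies, so every profile is accepted with
  # probability exactly a_frame / (W * H) irrespective of its position
  fs <- grid$frame_side
  fx0 <- grid$frame_u[1] * W; fy0 <- grid$frame_u[2] * H
  fx1 <- fx0 + fs; fy1 <- fy0 + fs
  Q <- c(leydig = 0L, sertoli = 0L, germ = 0L)
  if (nrow(cells)) {
    reps <- expand.grid(ox = c(-W, 0, W), oy = c(-H, 0, H))
    cx <- rep(cells$x, nrow(reps)) + rep(reps$ox, each = nrow(cells))
    cy <- rep(cells$y, nrow(reps)) + rep(reps$oy, each = nrow(cells))
    cr <- rep(cells$r, nrow(reps))
    ccl <- rep(cells$class, nrow(reps))
    dist_rect <- .point_rect_distance(cx, cy, fx0, fy0, fx1, fy1)
    # forbidden set: bottom edge extended to -Inf in x, right edge extended
    # to +Inf in y
    d_bottom <- ifelse(cx <= fx1, abs(cy - fy0),
                       sqrt((cx - fx1)^2 + (cy - fy0)^2))
    d_right <- ifelse(cy >= fy0, abs(cx - fx1),
                      sqrt((cx - fx1)^2 + (cy - fy0)^2))
    accept <- (dist_rect <= cr) & (pmin(d_bottom, d_right) > cr)
    if (any(accept)) {
      tb <- table(ccl[accept])
      Q[names(tb)] <- Q[names(tb)] + as.integer(tb)
    }
  }

  structure(list(
    P = P, SP = sum(P), P_cell = P_cell,
    I = I, I_luminal = if (luminal_surface) I_lum else NA_integer_,
    Q = Q, a_frame = grid$a_frame,
    L = grid$total_test_line, d = d
  ), class = "count_record")
}

#' @export
print.count_record <- function(x, ...) {
  cat(sprintf("<count_record> P: epi %d, lumen %d, int %d (SP %d); I = %d; Q: ley %d, ser %d, germ %d\n",
              x$P[["epithelium"]], x$P[["lumen"]], x$P[["interstitium"]],
              x$SP, x$I, x$Q[["leydig"]], x$Q[["sertoli"]], x$Q[["germ"]]))
  invisible(x)
}

# Cochran ratio-estimator CE for R = sum(x)/sum(y) over fields (relative).
.ratio_ce <- function(x, y) {
  n <- length(x)
  R <- sum(x) / sum(y)
  if (n < 2 || R == 0) return(0)
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  v <- (sxx + R^2 * syy - 2 * R * sxy) / (n * mean(y)^2)
  sqrt(max(v, 0)) / R
}

#' Volume density from pooled point counts
#'
#' `V_V(c) = sum(P_c) / sum(SP)` pooled over fields, for the three tissue
#' compartments and (with the same point grid against the overlaid cell
#' labels) the cell classes. The per-estimate CE is the Cochran
#' ratio-estimator coefficient of error across fields.
#'
#' @param records List of [count_field()] records.
#' @return Object of class `vv_estimate`: data frame with `compartment`,
#'   `vv` (fraction), `vv_pct`, `ce` (relative), `n_fields`.
#' @export
estimate_vv <- function(records) {
  stopifnot(length(records) >= 1,
            all(vapply(records, inherits, TRUE, "count_record")))
  SP <- vapply(records, function(r) as.numeric(r$SP), 0)
  if (sum(SP) == 0) stop("no test points landed on tissue")
  rows <- list()
  for (cp in c("epithelium", "lumen", "interstitium")) {
    x <- vapply(records, function(r) as.numeric(r$P[[cp]]), 0)
    rows[[cp]] <- data.frame(compartment = cp, vv = sum(x) / sum(SP),
                             ce = .ratio_ce(x, SP))
  }
  for (cl in c("leydig", "sertoli", "germ")) {
    x <- vapply(records, function(r) as.numeric(r$P_cell[[cl]]), 0)
    rows[[cl]] <- data.frame(compartment = cl, vv = sum(x) / sum(SP),
                             ce = .ratio_ce(x, SP))
  }
  out <- do.call(rbind, rows)
  out$vv_pct <- 100 * out$vv
  out$n_fields <- length(records)
  rownames(out) <- NULL
  class(out) <- c("vv_estimate", "data.frame")
  out
}

#' Surface density from intersection counts
#'
#' `S_V = 2 * sum(I) / L_tot` with `L_tot` the total test-line length over
#' all fields (the synthetic fields are all tissue, so the full line length
#' is tissue-restricted length). In a 2D section the boundary length density
#' obeys `B_A = (pi / 4) * S_V`, which serves as the oracle identity.
#'
#' @param records List of [count_field()] records.
#' @param luminal Use the luminal intersection counts instead of the outer
#'   boundary.
#' @return Object of class `sv_estimate`: `sv` (1/mm), `ce`, `sum_I`,
#'   `L_tot` (um), `n_fields`.
#' @export
estimate_sv <- function(records, luminal = FALSE) {
  stopifnot(length(records) >= 1)
  I <- vapply(records, function(r) {
    v <- if (luminal) r$I_luminal else r$I
    as.numeric(v)
  }, 0)
  if (anyNA(I)) stop("luminal intersections were not counted")
  L <- vapply(records, function(r) r$L, 0)
  L_tot <- sum(L)
  if (L_tot == 0) stop("total test line length is zero")
  structure(list(
    sv = 2 * sum(I) / L_tot * 1000,   # 1/um -> 1/mm
    ce = .ratio_ce(I, L),
    sum_I = sum(I), L_tot = L_tot, n_fields = length(records)
  ), class = "sv_estimate")
}

#' @export
print.sv_estimate <- function(x, ...) {
  cat(sprintf("<sv_estimate> S_V = %.2f /mm from %d intersections over %.0f um of test line (CE %.2f%%)\n",
              x$sv, x$sum_I, x$L_tot, 100 * x$ce))
  invisible(x)
}

#' Numerical density from counting-frame counts
#'
#' `Q_A = sum(Q) / (n_fields * a_frame)` per cell class, in profiles per
#' mm^2.
#'
#' @param records List of [count_field()] records.
#' @return Object of class `qa_estimate`: data frame with `class`, `qa`
#'   (per mm^2), `ce`, `sum_Q`, `n_fields`.
#' @export
estimate_qa <- function(records) {
  stopifnot(length(records) >= 1)
  a <- vapply(records, function(r) r$a_frame, 0)
  if (any(a <= 0)) stop("frame area must be positive")
  rows <- lapply(c("leydig", "sertoli", "germ"), function(cl) {
    q <- vapply(records, function(r) as.numeric(r$Q[[cl]]), 0)
    data.frame(class = cl,
               qa = sum(q) / (sum(a) / 1e6),   # um^2 -> mm^2
               ce = .ratio_ce(q, a),
               sum_Q = sum(q))
  })
  out <- do.call(rbind, rows)
  out$n_fields <- length(records)
  class(out) <- c("qa_estimate", "data.frame")
  out
}

#' Absolute compartment volume
#'
#' `V_ABS = V_V * Vol_REF`, with the CE propagated in quadrature from the
#' volume-density and reference-volume CEs.
#'
#' @param v_v Volume density as a fraction in `[0, 1]`.
#' @param vol_ref Reference volume (mm^3).
#' @param ce_vv,ce_ref Relative CEs of the two inputs.
#' @return Object of class `vabs_estimate`: `v_abs` (mm^3), `ce`.
#' @export
absolute_volume <- function(v_v, vol_ref, ce_vv = 0, ce_ref = 0) {
  stopifnot(v_v >= 0, v_v <= 1, vol_ref >= 0, ce_vv >= 0, ce_ref >= 0)
  structure(list(v_abs = v_v * vol_ref,
                 ce = sqrt(ce_vv^2 + ce_ref^2)),
            class = "vabs_estimate")
}

#' Decompose group variation into biology and estimation error
#'
#' `OCV` is the observed coefficient of variation of the per-animal values
#' (percent); `OCE` is the root-mean-square of the individual estimation
#' CEs (percent); the biological CV follows by subtraction in quadrature,
#' floored at zero.
#'
#' @param values Per-animal estimates (length >= 2).
#' @param ces Per-animal relative CEs (fractions, same length).
#' @return Object of class `precision_report`: `ocv_group`,
#'   `oce_individual`, `cv_biological` (all percent).
#' @export
precision_decomposition <- function(values, ces) {
  stopifnot(length(values) == length(ces), all(ces >= 0))
  if (length(values) < 2) stop("need at least 2 animals")
  m <- mean(values)
  ocv <- if (m == 0) 0 else 100 * stats::sd(values) / m
  oce <- 100 * sqrt(mean(ces^2))
  structure(list(
    ocv_group = ocv,
    oce_individual = oce,
    cv_biological = sqrt(max(ocv^2 - oce^2, 0))
  ), class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf("<precision_report> OCV %.2f%%, OCE %.2f%%, biological CV %.2f%%\n",
              x$ocv_group, x$oce_individual, x$cv_biological))
  invisible(x)
}
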
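# Multi-pair project management, cross-pair aggregation and reports.

#' Run the full pipeline on one wing pair
#'
#' load -> binarize -> mirror the designated left image -> scale ->
#' segment (cells, outline, skeleton junctions) -> superimpose (automatic
#' PSO, or a manual transform) -> evaluate all asymmetry metrics (and
#' per-set metrics if cell sets are supplied). Wing 1 is the reference.
#'
#' @param image1,image2 File paths or `wa_raw` objects. Both images must
#'   share the same dimensions.
#' @param label Pair label used in reports.
#' @param mirror Which image to mirror before analysis: `"first"`,
#'   `"second"` or `"none"`. A left wing is mirrored so both wings share
#'   the same orientation.
#' @param threshold Binarization threshold (default 0.54).
#' @param scale Optional length units per pixel.
#' @param min_cell_area Minimum cell area in px (default 8).
#' @param superimpose `"auto"` (PSO) or `"manual"`.
#' @param transform `wa_transform` used when `superimpose = "manual"`.
#' @param pso `wa_pso_config` for the automatic mode.
#' @param sets1,sets2 Optional cell-set specifications (as accepted by
#'   [assign_sets()]: `list(mode =, sets =)`), one per wing.
#' @param prune_spurs Skeleton spur-pruning length (px).
#' @param clean If `TRUE` (default), apply one [despeckle()] pass after
#'   binarization to suppress salt-and-pepper artifacts.
#' @return A `wa_pair` object: list with `label`, `wing1`, `wing2`
#'   (geometries), `transform`, `pso` (fit info or `NULL`), `result`
#'   (`wa_pair_result`) and `set_results` (data frame or `NULL`).
#' @export
run_pair <- function(image1, image2, label = "pair",
                     mirror = c("first", "second", "none"),
                     threshold = 0.54, scale = NULL, min_cell_area = 8,
                     superimpose = c("auto", "manual"),
                     transform = rigid_transform(), pso = pso_config(),
                     sets1 = NULL, sets2 = NULL, prune_spurs = 5,
                     clean = TRUE) {
  mirror <- match.arg(mirror)
  superimpose <- match.arg(superimpose)
  raw1 <- if (inherits(image1, "wa_raw")) image1 else load_image(image1)
  raw2 <- if (inherits(image2, "wa_raw")) image2 else load_image(image2)
  if (raw1$height != raw2$height || raw1$width != raw2$width)
    stop("pair images must share dimensions (pair '", label, "')")

  b1 <- binarize(raw1, threshold)
  b2 <- binarize(raw2, threshold)
  if (clean) {
    b1 <- despeckle(b1)
    b2 <- despeckle(b2)
  }
  if (mirror == "first") b1 <- mirror_horizontal(b1)
  if (mirror == "second") b2 <- mirror_horizontal(b2)
  if (!is.null(scale)) {
    b1 <- set_scale(b1, scale)
    b2 <- set_scale(b2, scale)
  }

  w1 <- segment_all(b1, min_cell_area = min_cell_area,
                    prune_spurs = prune_spurs)
  w2 <- segment_all(b2, min_cell_area = min_cell_area,
                    prune_spurs = prune_spurs)

  fit <- NULL
  if (superimpose == "auto") {
    fit <- pso_superimpose(w1, w2, pso)
    transform <- fit$transform
  }
  result <- evaluate_pair(w1, w2, transform, n_points = pso$n_points)

  set_results <- NULL
  if (!is.null(sets1) && !is.null(sets2)) {
    p1 <- assign_sets(w1, sets1$sets, mode = sets1$mode)
    p2 <- assign_sets(w2, sets2$sets, mode = sets2$mode)
    set_results <- evaluate_sets(w1, w2, p1, p2, transform)
  }

  structure(list(label = label, wing1 = w1, wing2 = w2,
                 transform = transform, pso = fit, result = result,
                 set_results = set_results),
            class = "wa_pair")
}

#' Run a project of several wing pairs
#'
#' @param pairs List of argument lists for [run_pair()]; each must carry a
#'   unique `label`.
#' @return A `wa_project`: list of `wa_pair` objects keyed by label.
#' @export
run_project <- function(pairs) {
  labels <- vapply(pairs, function(p) p$label %||% "pair", "")
  if (anyDuplicated(labels)) stop("pair labels must be unique")
  out <- lapply(pairs, function(p) do.call(run_pair, p))
  names(out) <- labels
  structure(out, class = "wa_project")
}

#' Aggregate results across the pairs of a project
#'
#' Builds long-format tables of the per-pair metrics for cross-pair
#' comparison: regression/NRMSE rows per pair x direction x metric,
#' distance statistics, count and whole-wing deltas, per-set rows, and a
#' min/median/max summary of the box-plot quantities.
#'
#' @param project A `wa_project` (or a list of `wa_pair` objects).
#' @return A `wa_aggregate`: list of data frames `metrics`, `distances`,
#'   `deltas`, `sets` (possibly empty) and `summary`.
#' @export
aggregate_project <- function(project) {
  stopifnot(length(project) >= 1)
  metrics <- do.call(rbind, lapply(project, function(p)
    cbind(pair = p$label, p$result$metrics)))
  distances <- do.call(rbind, lapply(project, function(p)
    cbind(pair = p$label, p$result$distances)))
  deltas <- do.call(rbind, lapply(project, function(p)
    data.frame(pair = p$label, t(p$result$deltas))))
  sets <- do.call(rbind, lapply(project, function(p)
    if (is.null(p$set_results)) NULL else
      cbind(pair = p$label, p$set_results)))
  num <- function(x) x[vapply(x, is.numeric, TRUE)]
  summarize <- function(df) {
    cols <- num(df)
    data.frame(quantity = names(cols),
               min = vapply(cols, min, 1, na.rm = TRUE),
               median = vapply(cols, function(v) median(v, na.rm = TRUE), 1),
               max = vapply(cols, max, 1, na.rm = TRUE),
               row.names = NULL)
  }
  structure(list(metrics = metrics, distances = distances, deltas = deltas,
                 sets = sets,
                 summary = rbind(cbind(table = "metrics", summarize(metrics)),
                                 cbind(table = "distances", summarize(distances)))),
            class = "wa_aggregate")
}

#' @importFrom stats median
fmt9 <- function(df) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- formatC(df[[j]], digits = 9, format = "g")
  df
}

wcsv <- function(df, path) write.csv(fmt9(df), path, row.names = FALSE)

#' Write per-pair and aggregate reports
#'
#' For each pair: wing specification tables (cells, junctions, wing
#' summary), comparison tables per reference direction, distance and delta
#' tables, transform, and per-set tables when present -- as CSV, plus a
#' human-readable TXT rendering of the same content. A cross-pair
#' aggregate CSV covers the whole project. Output is byte-stable for
#' identical inputs.
#'
#' @param project A `wa_project` (or list of `wa_pair`).
#' @param out_dir Output directory (created if missing).
#' @param formats Subset of `c("csv", "txt")`.
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(project, out_dir, formats = c("csv", "txt")) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    wcsv(df, p)
    paths <<- c(paths, p)
  }
  for (p in project) {
    lb <- p$label
    for (k in 1:2) {
      w <- if (k == 1) p$wing1 else p$wing2
      if ("csv" %in% formats) {
        emit(w$cells, sprintf("pair_%s_wing%d.csv", lb, k))
        emit(w$junctions, sprintf("pair_%s_wing%d_junctions.csv", lb, k))
        emit(data.frame(n_cells = w$n_cells, n_junctions = w$n_junctions,
                        wing_area = w$wing_area, wing_length = w$wing_length,
                        wing_width = w$wing_width,
                        wing_perimeter = w$wing_perimeter, scale = w$scale),
             sprintf("pair_%s_wing%d_summary.csv", lb, k))
      }
    }
    if ("csv" %in% formats) {
      for (d in 1:2)
        emit(p$result$metrics[p$result$metrics$direction == d,
                              setdiff(names(p$result$metrics), "direction")],
             sprintf("pair_%s_compare_ref%d.csv", lb, d))
      emit(p$result$distances, sprintf("pair_%s_distances.csv", lb))
      emit(data.frame(quantity = names(p$result$deltas),
                      value = unname(p$result$deltas)),
           sprintf("pair_%s_deltas.csv", lb))
      emit(data.frame(x = p$transform$x, y = p$transform$y,
                      theta_degrees = p$transform$theta * 180 / pi),
           sprintf("pair_%s_transform.csv", lb))
      if (!is.null(p$set_results))
        emit(p$set_results, sprintf("pair_%s_sets.csv", lb))
    }
    if ("txt" %in% formats) {
      tp <- file.path(out_dir, sprintf("pair_%s_report.txt", lb))
      writeLines(render_txt(p), tp)
      paths <- c(paths, tp)
    }
  }
  if ("csv" %in% formats && length(project) >= 1) {
    agg <- aggregate_project(project)
    emit(agg$metrics, "aggregate_metrics.csv")
    emit(agg$distances, "aggregate_distances.csv")
    emit(agg$deltas, "aggregate_deltas.csv")
    if (!is.null(agg$sets)) emit(agg$sets, "aggregate_sets.csv")
    emit(agg$summary, "aggregate_summary.csv")
  }
  invisible(paths)
}

render_txt <- function(p) {
  num <- function(x) formatC(x, digits = 9, format = "g")
  out <- c(sprintf("Wing pair report: %s", p$label), strrep("=", 40), "")
  for (k in 1:2) {
    w <- if (k == 1) p$wing1 else p$wing2
    out <- c(out, sprintf("Wing %d specification", k),
             sprintf("  cells: %d  junctions: %d", w$n_cells, w$n_junctions),
             sprintf("  wing area: %s  length: %s  width: %s  perimeter: %s",
                     num(w$wing_area), num(w$wing_length), num(w$wing_width),
                     num(w$wing_perimeter)),
             sprintf("  scale: %s units/px", num(w$scale)), "")
  }
  out <- c(out, sprintf("Superimposition: x = %s  y = %s  theta = %s deg",
                        num(p$transform$x), num(p$transform$y),
                        num(p$transform$theta * 180 / pi)), "")
  for (d in 1:2) {
    out <- c(out, sprintf("Comparison (reference = wing %d)", d))
    m <- p$result$metrics[p$result$metrics$direction == d, ]
    for (i in seq_len(nrow(m)))
      out <- c(out, sprintf("  %-12s slope = %s  intercept = %s  r2 = %s  nrmse = %s",
                            m$metric[i], num(m$slope[i]), num(m$intercept[i]),
                            num(m$r2[i]), num(m$nrmse[i])))
    dd <- p$result$distances[p$result$distances$direction == d, ]
    for (i in seq_len(nrow(dd)))
      out <- c(out, sprintf("  %-12s n = %d  mean dist = %s  sd = %s",
                            dd$category[i], dd$n[i], num(dd$mean[i]),
                            num(dd$sd[i])))
    out <- c(out, "")
  }
  out <- c(out, "Count and size differences (wing1 - wing2)")
  for (nm in names(p$result$deltas))
    out <- c(out, sprintf("  %-22s %s", nm, num(p$result$deltas[[nm]])))
  if (!is.null(p$set_results)) {
    out <- c(out, "", "Cell-set comparison")
    s <- p$set_results
    for (i in seq_len(nrow(s)))
      out <- c(out, sprintf("  %s dir %d %-12s r2 = %s  nrmse = %s",
                            s$set_label[i], s$direction[i], s$metric[i],
                            num(s$r2[i]), num(s$nrmse[i])))
  }
  out
}

#' @export
print.wa_pair <- function(x, ...) {
  cat("<wa_pair> '", x$label, "': ", x$wing1$n_cells, " vs ",
      x$wing2$n_cells, " cells\n", sep = "")
  print(x$result)
  invisible(x)
}
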
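# Readers/writers for the plain-text exchange formats (waveform table, ESRI
# ASCII grid, CSV tables) and the end-to-end pipeline driver.
#
# Coordinate convention, used everywhere: cell-centre coordinates in meters,
# easting/northing, row 1 = north edge; 0-based class labels in discretized
# responses; all interval bins right-open except the last.

#' Write / read a plain-text waveform table
#'
#' Format: one header line `sounding_id easting northing t0 dt n
#' intensities...`, then one space-separated row per sounding:
#' `sounding_id easting northing t0 dt n i1 i2 ... in`.
#'
#' @param waveforms list of `bs_waveform` objects.
#' @param path file path.
#' @return `read_waveform_table` returns a list of `bs_waveform`;
#'   `write_waveform_table` returns `path` invisibly.
#' @export
write_waveform_table <- function(waveforms, path) {
  hdr <- "sounding_id easting northing t0 dt n intensities..."
  num <- function(x) sprintf("%.17g", x)  # lossless double round-trip
  rows <- vapply(waveforms, function(w) {
    paste(w$sounding_id, num(w$easting), num(w$northing), num(w$t0),
          num(w$dt), length(w$intensities),
          paste(num(w$intensities), collapse = " "))
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_waveform_table
#' @export
read_waveform_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "sounding_id")) {
    stop("malformed waveform table header at line 1 of ", path,
         call. = FALSE)
  }
  out <- vector("list", length(lines) - 1)
  for (i in seq_along(out)) {
    tok <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    if (length(tok) < 7) {
      stop("malformed waveform row at line ", i + 1, " of ", path,
           call. = FALSE)
    }
    n <- as.integer(tok[6])
    if (is.na(n) || length(tok) != 6 + n) {
      stop("sample count mismatch at line ", i + 1, " of ", path,
           call. = FALSE)
    }
    out[[i]] <- structure(
      list(t0 = as.numeric(tok[4]), dt = as.numeric(tok[5]),
           intensities = as.numeric(tok[7:(6 + n)]),
           sounding_id = tok[1],
           easting = as.numeric(tok[2]), northing = as.numeric(tok[3])),
      class = "bs_waveform")
  }
  out
}

#' Write / read an ESRI ASCII grid
#'
#' Standard `.asc` layout (ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value header, rows north to south), preserving grid geometry and
#' no-data cells.
#'
#' @param grid a `bs_grid` (or numeric matrix, with `cell_size`/`origin`).
#' @param path file path.
#' @param cell_size,origin used when `grid` is a bare matrix.
#' @return `read_ascii_grid` returns a `bs_grid`; the writer returns `path`
#'   invisibly.
#' @export
write_ascii_grid <- function(grid, path, cell_size = 2, origin = NULL) {
  if (inherits(grid, "bs_grid")) {
    vals <- grid$values; cs <- grid$cell_size; org <- grid$origin
  } else {
    vals <- grid; cs <- cell_size
    org <- if (is.null(origin)) c(0, nrow(vals) * cs) else origin
  }
  nodata <- -9999
  v <- vals
  v[is.na(v)] <- nodata
  num <- function(x) sprintf("%.17g", x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(vals)),
    paste("nrows", nrow(vals)),
    paste("xllcorner", num(org[1])),
    paste("yllcorner", num(org[2] - nrow(vals) * cs)),
    paste("cellsize", num(cs)),
    paste("NODATA_value", nodata)), con)
  writeLines(apply(v, 1, function(r) paste(num(r), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) != 2 || is.na(suppressWarnings(as.numeric(tok[2])))) {
      stop("malformed ASCII grid header at line ", i, " of ", path,
           call. = FALSE)
    }
    hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr))) {
    stop("incomplete ASCII grid header in ", path, call. = FALSE)
  }
  vals <- matrix(scan(text = lines[-(1:6)], quiet = TRUE),
                 nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  vals[vals == hdr$nodata_value] <- NA
  new_grid(vals, hdr$cellsize,
           origin = c(hdr$xllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize))
}

#' Write / read a categorical raster
#'
#' The class codes go into an ESRI ASCII grid; the legend is stored alongside
#' as `<path>.legend` (one label per line, in code order).
#'
#' @param raster a `bs_raster_cat`.
#' @param path `.asc` file path.
#' @return `read_categorical_raster` returns a `bs_raster_cat`.
#' @export
write_categorical_raster <- function(raster, path) {
  write_ascii_grid(new_grid(raster$codes + 0, raster$cell_size,
                            raster$origin), path)
  writeLines(raster$legend, paste0(path, ".legend"))
  invisible(path)
}

#' @rdname write_categorical_raster
#' @export
read_categorical_raster <- function(path) {
  g <- read_ascii_grid(path)
  legend <- readLines(paste0(path, ".legend"))
  codes <- matrix(as.integer(round(g$values)), nrow(g$values))
  new_categorical_raster(codes, legend, g$cell_size, g$origin)
}

# waveforms over every grid cell, seeded once
simulate_cell_waveforms <- function(scape, seed) {
  R <- nrow(scape$depth$values); C <- ncol(scape$depth$values)
  cfg <- scape$config
  with_seed(seed, {
    out <- vector("list", R * C)
    n <- 0L
    for (j in seq_len(C)) for (i in seq_len(R)) {
      n <- n + 1L
      xy <- cell_coords(scape$depth, i, j)
      out[[n]] <- simulate_waveform(
        scape$depth$values[i, j], scape$complexity$values[i, j],
        noise_sd = cfg$waveform_noise_sd, seed = NULL,
        sounding_id = sprintf("c%03d_%03d", i, j),
        easting = xy$easting, northing = xy$northing)
    }
    out
  })
}

# parse "c<row>_<col>" sounding ids back to cells
sounding_cells <- function(ids) {
  m <- regmatches(ids, regexec("^c([0-9]+)_([0-9]+)$", ids))
  data.frame(row = vapply(m, function(x) as.integer(x[2]), integer(1)),
             col = vapply(m, function(x) as.integer(x[3]), integer(1)))
}

#' Assemble the per-cell predictor table
#'
#' Joins mean bathymetry, the 12 morphometric layers (flat-cell aspect
#' recoded to 0), the two terrain-class maps, the substratum class and its
#' kernel Bray-Curtis / evenness values, and the 16 waveform features into
#' the standard 34-column predictor table, one row per cell present in
#' `features`.
#'
#' @param features waveform feature table with `sounding_id` in
#'   `c<row>_<col>` form and a `depth` column.
#' @param morpho a `bs_morpho` stack.
#' @param terrain6,terrain12 `bs_raster_cat` terrain maps.
#' @param substratum `bs_raster_cat` substratum map.
#' @param bc,evenness matrices from [kernel_braycurtis()] /
#'   [kernel_evenness()].
#' @return Data.frame with `row`, `col` and 34 predictor columns.
#' @export
predictor_table <- function(features, morpho, terrain6, terrain12,
                            substratum, bc, evenness) {
  cells <- sounding_cells(features$sounding_id)
  ij <- cbind(cells$row, cells$col)
  lay <- morpho$layers
  asp <- lay$aspect[ij]
  asp[is.na(asp)] <- 0
  out <- data.frame(
    row = cells$row, col = cells$col,
    bathymetry = features$depth,
    abs_roughness = lay$abs_roughness[ij],
    local_roughness = lay$local_roughness[ij],
    slope = lay$slope[ij], aspect = asp,
    shaded_relief = lay$shaded_relief[ij],
    profile_convexity = lay$profile_convexity[ij],
    plan_convexity = lay$plan_convexity[ij],
    longitudinal_convexity = lay$longitudinal_convexity[ij],
    cross_sectional_convexity = lay$cross_sectional_convexity[ij],
    min_curvature = lay$min_curvature[ij],
    max_curvature = lay$max_curvature[ij],
    rmse = lay$rmse[ij],
    terrain_6m = as.numeric(terrain6$codes[ij]),
    terrain_12m = as.numeric(terrain12$codes[ij]),
    substratum = as.numeric(substratum$codes[ij]),
    substratum_bc = bc[ij],
    substratum_evenness = evenness[ij])
  cbind(out, features[waveform_feature_names()])
}

#' Run the full analysis pipeline on a synthetic survey
#'
#' Simulate -> waveform features -> diversity indices -> morphometry ->
#' substratum map and kernel beta-diversity -> learner benchmark -> model
#' selection -> Moran's I -> predictive map. All stages are seeded from
#' `config$seed`; reruns are bit-identical. When `out_dir` is given, every
#' product is also written there (CSV tables, ASCII grids, the waveform
#' table, and a `manifest` of counts and seeds).
#'
#' @param config a [benthoscape_config()].
#' @param out_dir optional output directory.
#' @param responses response columns to benchmark (default all 8).
#' @param learners learners to benchmark.
#' @param ks class counts to sweep.
#' @param test_n held-out test size.
#' @param kernel_radius_m radius for the kernel diversity rasters.
#' @return List with all stage products (`scape`, `stations`, `quadrats`,
#'   `indices`, `features`, `pcs`, `substratum_map`, `substratum_accuracy`,
#'   `bc`, `evenness`, `morpho`, `terrain6`, `terrain12`, `predictors`,
#'   `cube`, `selected`, `moran`, `predicted_map`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         responses = response_names(),
                         learners = learner_names(), ks = 2:10,
                         test_n = 100, kernel_radius_m = 6) {
  seed <- config$seed
  scape <- generate_benthoscape(config)
  stations <- sample_stations(scape, config$n_stations, seed = seed + 1L)
  quadrats <- generate_quadrats(stations, config)
  indices <- index_table(quadrats, quadrat_area = config$quadrat_area,
                         biotic = config$species_pool)

  waveforms <- simulate_cell_waveforms(scape, seed = seed + 2L)
  cells_all <- sounding_cells(vapply(waveforms, `[[`, character(1),
                                     "sounding_id"))
  depths_all <- scape$depth$values[cbind(cells_all$row, cells_all$col)]
  features <- extract_feature_table(waveforms, depths = depths_all)
  resid <- depth_normalize(features)
  pcs <- pca_reduce(resid)

  # substratum mapping from the waveform PCs
  gt <- sample_ground_truth(scape$substratum, n_per_class = 60,
                            seed = seed + 3L)
  pc_cells <- cbind(sounding_cells(pcs$sounding_id),
                    pcs[grep("^PC", names(pcs))])
  key <- paste(pc_cells$row, pc_cells$col)
  gt$cell_idx <- match(paste(gt$row, gt$col), key)
  gt <- gt[!is.na(gt$cell_idx), ]
  tr <- gt$split == "train"
  pc_mat <- as.matrix(pc_cells[grep("^PC", names(pc_cells))])
  svm_model <- train_substratum_classifier(pc_mat[gt$cell_idx[tr], ,
                                                  drop = FALSE],
                                           gt$label[tr], seed = seed + 4L)
  substratum_map <- classify_seafloor(svm_model, pc_cells,
                                      config$grid_shape,
                                      cell_size = config$cell_size)
  va <- gt[!tr, ]
  pred_va <- substratum_map$legend[
    substratum_map$codes[cbind(va$row, va$col)]]
  sub_acc <- confusion_matrix(pred_va, va$label,
                              classes = scape$substratum$legend)

  bc <- kernel_braycurtis(substratum_map, kernel_radius_m)
  evenness <- kernel_evenness(substratum_map, kernel_radius_m)

  morpho <- morpho_stack(scape$depth)
  terrain6 <- classify_terrain(scape$depth, 6)
  terrain12 <- classify_terrain(scape$depth, 12)

  stack_cells <- predictor_table(features, morpho, terrain6, terrain12,
                                 substratum_map, bc, evenness)
  stn_idx <- match(paste(stations$row, stations$col),
                   paste(stack_cells$row, stack_cells$col))
  if (anyNA(stn_idx)) {
    stop("pipeline stage 'features': station cell lost its bottom signal",
         call. = FALSE)
  }
  predictors <- stack_cells[stn_idx, setdiff(names(stack_cells),
                                             c("row", "col"))]
  rownames(predictors) <- NULL

  cube <- sweep_learners(predictors, indices[responses],
                         learners = learners, ks = ks, test_n = test_n,
                         seed = seed + 5L)
  selected <- select_model(cube)

  moran <- morans_i(indices$D, coords = stations[c("easting", "northing")],
                    seed = seed + 6L)

  disc <- equal_width_discretize(indices[[selected$response]], selected$k,
                                 range = if (selected$response == "D")
                                   c(0, 1) else NULL)
  split <- split_train_test(nrow(predictors), test_n = test_n,
                            seed = seed + 5L)
  predicted_map <- predict_map(
    selected$learner, predictors[split$train, , drop = FALSE],
    disc$labels[split$train], selected$k,
    stack_cells, config$grid_shape, edges = disc$edges,
    cell_size = config$cell_size, seed = seed + 5L)

  manifest <- list(
    config = unclass(config), seed = seed,
    n_stations = nrow(stations), n_soundings = length(waveforms),
    n_lost = attr(features, "n_lost"),
    n_cells = prod(config$grid_shape),
    bench_cells = nrow(cube), bench_failures = sum(!is.na(cube$error)),
    selected = as.list(selected))

  out <- list(scape = scape, stations = stations, quadrats = quadrats,
              indices = indices, features = features, pcs = pcs,
              substratum_map = substratum_map, substratum_accuracy = sub_acc,
              bc = bc, evenness = evenness, morpho = morpho,
              terrain6 = terrain6, terrain12 = terrain12,
              predictors = predictors, cube = cube, selected = selected,
              moran = moran, predicted_map = predicted_map,
              manifest = manifest)

  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir, waveforms)
  out
}

write_pipeline_outputs <- function(out, out_dir, waveforms) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write.csv(out$stations, p("stations.csv"), row.names = FALSE)
  write.csv(out$quadrats, p("quadrats.csv"), row.names = FALSE)
  write.csv(out$indices, p("indices.csv"), row.names = FALSE)
  write.csv(out$features, p("waveform_features.csv"), row.names = FALSE)
  write.csv(cbind(out$stations[c("station_id")], out$predictors),
            p("predictors.csv"), row.names = FALSE)
  write.csv(as.data.frame(out$cube), p("eval_cube.csv"), row.names = FALSE)
  write.csv(out$selected, p("selected_model.csv"), row.names = FALSE)
  write_ascii_grid(out$scape$depth, p("depth.asc"))
  write_ascii_grid(out$scape$complexity, p("complexity.asc"))
  write_categorical_raster(out$scape$substratum, p("substratum_truth.asc"))
  write_categorical_raster(out$substratum_map, p("substratum_map.asc"))
  write_ascii_grid(out$bc, p("braycurtis.asc"),
                   cell_size = out$scape$depth$cell_size)
  write_ascii_grid(out$evenness, p("evenness.asc"),
                   cell_size = out$scape$depth$cell_size)
  write_categorical_raster(out$terrain6, p("terrain_6m.asc"))
  write_categorical_raster(out$terrain12, p("terrain_12m.asc"))
  write_categorical_raster(out$predicted_map$class_map,
                           p("predicted_diversity.asc"))
  write_waveform_table(waveforms, p("waveforms.txt"))
  man <- out$manifest
  man$config$species_pool <- paste(man$config$species_pool, collapse = ";")
  man$config$abiotic_pool <- paste(man$config$abiotic_pool, collapse = ";")
  writeLines(paste(names(unlist(man)), unlist(man), sep = "\t"),
             p("manifest.tsv"))
  invisible(out_dir)
}
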
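#' Default habitat class breakpoints
#'
#' Habitat classes are a step function of above-ground carbon (AGC). The only
#' anchored boundaries are the montane-forest threshold at 90 Mg C ha^-1 and
#' woodland around 20 Mg C ha^-1; the remaining breakpoints are calibration
#' knobs. Each entry gives the lower AGC bound (inclusive) of its class.
#'
#' @return Named numeric vector of lower class bounds, ascending.
#' @export
default_breakpoints <- function() {
  c(cropland = 0, woodland = 10, bushland = 40, montane_forest = 90)
}

#' Default breeding densities per habitat class
#'
#' Maximum number of adult birds breeding per 1-ha patch, by habitat class.
#' Values are even so that capacity divides into breeding-pair territories of
#' two slots. These are calibration defaults, not field estimates.
#'
#' @return Named numeric vector, adults per hectare.
#' @export
default_density_table <- function() {
  c(cropland = 2, woodland = 4, bushland = 6, montane_forest = 8)
}

#' Classify habitat from above-ground carbon
#'
#' Pure step function of AGC: montane forest at AGC >= 90 Mg C ha^-1, lower
#' classes from the breakpoint table below that.
#'
#' @param agc Numeric vector of AGC values (Mg C ha^-1), non-negative.
#' @param breakpoints Named vector of ascending lower class bounds, as
#'   [default_breakpoints()].
#' @return Character vector of class labels (`NA` for `NA` input).
#' @export
#' @examples
#' classify_habitat(c(5, 20, 60, 90, 150))
classify_habitat <- function(agc, breakpoints = default_breakpoints()) {
  if (any(agc < 0, na.rm = TRUE)) {
    abort("AGC values must be non-negative.")
  }
  if (is.unsorted(breakpoints) || breakpoints[[1]] != 0) {
    abort("`breakpoints` must be ascending and start at 0.")
  }
  idx <- findInterval(agc, breakpoints)
  names(breakpoints)[idx]
}

#' Carrying capacity of a patch
#'
#' Looks up the breeding density of the patch's habitat class. Deterministic
#' given the density table.
#'
#' @inheritParams classify_habitat
#' @param density_table Named vector mapping every habitat class to adults per
#'   hectare, as [default_density_table()].
#' @return Integer vector of capacities (adult birds per patch).
#' @export
carrying_capacity <- function(agc, density_table = default_density_table(),
                              breakpoints = default_breakpoints()) {
  cls <- classify_habitat(agc, breakpoints)
  missing_cls <- setdiff(unique(cls[!is.na(cls)]), names(density_table))
  if (length(missing_cls) > 0) {
    abort(paste0("`density_table` has no entry for habitat class: ",
                 paste(missing_cls, collapse = ", ")))
  }
  as.integer(unname(density_table[cls]))
}

new_landscape <- function(tbl, n_rows, n_cols, density_table, breakpoints) {
  structure(tbl,
            n_rows = n_rows, n_cols = n_cols,
            density_table = density_table, breakpoints = breakpoints,
            class = c("zos_landscape", class(tibble::tibble())))
}

#' Build a landscape from an AGC matrix
#'
#' One matrix cell is one 1-ha patch; row 1 is the northernmost row. `NA`
#' cells are treated as outside the study area (nodata) and are kept in the
#' table with missing habitat and zero capacity.
#'
#' @param agc Numeric matrix of AGC values (Mg C ha^-1); `NA` = nodata.
#' @param density_table,breakpoints See [carrying_capacity()].
#' @return A `zos_landscape`: a tibble with columns `row`, `col`, `agc`,
#'   `habitat`, `capacity` (row-major order) and attributes `n_rows`,
#'   `n_cols`, `density_table`, `breakpoints`.
#' @export
#' @examples
#' landscape(matrix(c(100, 20, 0, 250), 2, byrow = TRUE))
landscape <- function(agc, density_table = default_density_table(),
                      breakpoints = default_breakpoints()) {
  if (!is.matrix(agc)) abort("`agc` must be a matrix.")
  if (any(agc < 0, na.rm = TRUE)) abort("AGC values must be non-negative.")
  nr <- nrow(agc); nc <- ncol(agc)
  vals <- as.vector(t(agc)) # row-major
  habitat <- classify_habitat(vals, breakpoints)
  capacity <- integer(length(vals))
  ok <- !is.na(vals)
  capacity[ok] <- carrying_capacity(vals[ok], density_table, breakpoints)
  tbl <- tibble::tibble(
    row = rep(seq_len(nr), each = nc),
    col = rep(seq_len(nc), times = nr),
    agc = vals, habitat = habitat, capacity = capacity
  )
  new_landscape(tbl, nr, nc, density_table, breakpoints)
}

#' Extract a value matrix from a landscape
#'
#' @param ls A `zos_landscape`.
#' @param value Column to spread into a matrix (default `"agc"`).
#' @return Matrix of dimension `n_rows` x `n_cols`.
#' @export
landscape_matrix <- function(ls, value = "agc") {
  nr <- attr(ls, "n_rows"); nc <- attr(ls, "n_cols")
  matrix(ls[[value]], nrow = nr, ncol = nc, byrow = TRUE)
}

# row/col -> row-major cell index
cell_index <- function(ls, row, col) {
  (row - 1L) * attr(ls, "n_cols") + col
}

#' Read an AGC raster from a plain-text grid
#'
#' Accepts a whitespace-delimited numeric grid, optionally preceded by an
#' ESRI-ASCII-style header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `nodata_value`; any subset, case-insensitive). Cells equal to
#' the nodata value are masked.
#'
#' @param path Path to the grid file.
#' @param nodata_value Value marking cells outside the study area; a
#'   `nodata_value` header line in the file takes precedence.
#' @inheritParams landscape
#' @return A `zos_landscape`.
#' @export
read_agc_grid <- function(path, nodata_value = -9999,
                          density_table = default_density_table(),
                          breakpoints = default_breakpoints()) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header_keys <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                   "nodata_value")
  is_header <- function(x) {
    tolower(sub("\\s.*$", "", trimws(x))) %in% header_keys
  }
  n_head <- 0L
  while (n_head < length(lines) && is_header(lines[n_head + 1L])) {
    n_head <- n_head + 1L
  }
  header <- list()
  if (n_head > 0) {
    for (ln in lines[seq_len(n_head)]) {
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      header[[tolower(parts[1])]] <- as.numeric(parts[2])
    }
  }
  if (!is.null(header$nodata_value)) nodata_value <- header$nodata_value
  body <- lines[-seq_len(n_head)]
  if (n_head == 0) body <- lines
  if (length(body) == 0) abort(paste0("No grid rows found in ", path))
  rows <- lapply(strsplit(trimws(body), "\\s+"), as.numeric)
  widths <- lengths(rows)
  if (length(unique(widths)) != 1) {
    abort(paste0("Ragged grid in ", path, ": row widths ",
                 paste(unique(widths), collapse = ", ")))
  }
  if (anyNA(unlist(rows))) abort(paste0("Non-numeric grid cell in ", path))
  m <- do.call(rbind, rows)
  if (!is.null(header$nrows) && nrow(m) != header$nrows) {
    abort(paste0("Header declares ", header$nrows, " rows but file has ",
                 nrow(m)))
  }
  if (!is.null(header$ncols) && ncol(m) != header$ncols) {
    abort(paste0("Header declares ", header$ncols, " cols but file has ",
                 ncol(m)))
  }
  m[m == nodata_value] <- NA_real_
  if (any(m < 0, na.rm = TRUE)) {
    abort(paste0("Negative AGC values in ", path))
  }
  landscape(m, density_table, breakpoints)
}

#' Write a landscape's AGC raster as a plain-text grid
#'
#' Writes the same dialect [read_agc_grid()] reads: an ESRI-ASCII-style
#' header followed by whitespace-delimited rows; `NA` cells are written as
#' the nodata value.
#'
#' @param ls A `zos_landscape` (or a plain numeric matrix).
#' @param path Output file path.
#' @param nodata_value Value written for masked cells.
#' @param value Landscape column to write when `ls` is a landscape.
#' @return `path`, invisibly.
#' @export
write_agc_grid <- function(ls, path, nodata_value = -9999, value = "agc") {
  m <- if (is.matrix(ls)) ls else landscape_matrix(ls, value)
  m[is.na(m)] <- nodata_value
  header <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
              paste("nodata_value", format(nodata_value, scientific = FALSE)))
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE, scientific = FALSE),
                                        collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Detect montane forest fragments
#'
#' A fragment is a connected component (8-neighbour, queen adjacency) of
#' patches classified as montane forest. Fragments are labelled in decreasing
#' area order; one patch is one hectare.
#'
#' @param ls A `zos_landscape`.
#' @return Tibble with columns `fragment` (integer id), `area_ha`,
#'   `centroid_row`, `centroid_col`, and a list-column `patches` of
#'   `(row, col)` tibbles. Zero rows if there is no forest.
#' @export
identify_fragments <- function(ls) {
  nr <- attr(ls, "n_rows"); nc <- attr(ls, "n_cols")
  forest <- !is.na(ls$habitat) & ls$habitat == "montane_forest"
  empty <- tibble::tibble(fragment = integer(), area_ha = integer(),
                          centroid_row = numeric(), centroid_col = numeric(),
                          patches = list())
  if (!any(forest)) return(empty)
  is_forest <- matrix(FALSE, nr, nc)
  is_forest[cbind(ls$row[forest], ls$col[forest])] <- TRUE
  label <- matrix(0L, nr, nc)
  cur <- 0L
  seeds <- which(is_forest, arr.ind = TRUE)
  for (k in seq_len(nrow(seeds))) {
    r0 <- seeds[k, 1]; c0 <- seeds[k, 2]
    if (label[r0, c0] != 0L) next
    cur <- cur + 1L
    # flood fill with an explicit queue over the (few) forest cells
    queue <- matrix(c(r0, c0), ncol = 2)
    label[r0, c0] <- cur
    while (nrow(queue) > 0) {
      r <- queue[1, 1]; cc <- queue[1, 2]
      queue <- queue[-1, , drop = FALSE]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; ccc <- cc + dc
        if (rr < 1 || rr > nr || ccc < 1 || ccc > nc) next
        if (is_forest[rr, ccc] && label[rr, ccc] == 0L) {
          label[rr, ccc] <- cur
          queue <- rbind(queue, c(rr, ccc))
        }
      }
    }
  }
  cells <- which(label != 0L, arr.ind = TRUE)
  comp <- label[cells]
  frag <- tibble::tibble(row = cells[, 1], col = cells[, 2], comp = comp) |>
    dplyr::group_by(.data$comp) |>
    dplyr::summarise(area_ha = dplyr::n(),
                     centroid_row = mean(.data$row),
                     centroid_col = mean(.data$col),
                     patches = {
                       o <- order(.data$row, .data$col)
                       rr <- .data$row[o]; cc <- .data$col[o]
                       list(tibble::tibble(row = rr, col = cc))
                     },
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$area_ha), .data$centroid_row, .data$centroid_col) |>
    dplyr::mutate(fragment = dplyr::row_number()) |>
    dplyr::select("fragment", "area_ha", "centroid_row", "centroid_col", "patches")
  frag
}

#' Habitat-change scenario specification
#'
#' A named landscape transform: the listed target patches get a replacement
#' AGC value. Defaults follow the scenario's meaning: depletion and clearing
#' convert to woodland-level AGC (20 Mg C ha^-1), corridor planting and
#' plantation conversion create montane forest (100 Mg C ha^-1). `control`
#' transforms nothing.
#'
#' @param name One of `"control"`, `"edge_depletion"`, `"fragment_clearing"`,
#'   `"corridor_planting"`, `"plantation_conversion"`.
#' @param target_patches Tibble/data frame with columns `row`, `col`.
#' @param new_agc Replacement AGC; `NULL` uses the scenario default.
#' @return A `zos_scenario` object.
#' @export
scenario_spec <- function(name, target_patches = NULL, new_agc = NULL) {
  names_ok <- c("control", "edge_depletion", "fragment_clearing",
                "corridor_planting", "plantation_conversion")
  name <- match.arg(name, names_ok)
  defaults <- c(control = NA_real_, edge_depletion = 20, fragment_clearing = 20,
                corridor_planting = 100, plantation_conversion = 100)
  if (is.null(new_agc)) new_agc <- unname(defaults[[name]])
  if (name == "control") {
    target_patches <- tibble::tibble(row = integer(), col = integer())
  } else if (is.null(target_patches)) {
    abort(paste0("Scenario '", name, "' needs `target_patches`."))
  }
  target_patches <- tibble::as_tibble(target_patches)[, c("row", "col")]
  structure(list(name = name, target_patches = target_patches,
                 new_agc = new_agc),
            class = "zos_scenario")
}

#' Apply a habitat-change scenario to a landscape
#'
#' Returns a copy of the landscape in which every target patch's AGC is
#' replaced by the scenario value and habitat class and carrying capacity are
#' recomputed; all other patches are untouched.
#'
#' @param ls A `zos_landscape`.
#' @param spec A `zos_scenario` from [scenario_spec()], or a scenario name
#'   when `ls` carries generator-derived scenarios (see
#'   [generate_landscape()]).
#' @return The transformed `zos_landscape`.
#' @export
apply_scenario <- function(ls, spec) {
  if (is.character(spec)) {
    scen <- attr(ls, "scenarios")
    if (is.null(scen) || is.null(scen[[spec]])) {
      abort(paste0("Landscape carries no scenario named '", spec, "'."))
    }
    spec <- scen[[spec]]
  }
  stopifnot(inherits(spec, "zos_scenario"))
  tp <- spec$target_patches
  if (nrow(tp) == 0) return(ls)
  nr <- attr(ls, "n_rows"); nc <- attr(ls, "n_cols")
  if (any(tp$row < 1 | tp$row > nr | tp$col < 1 | tp$col > nc)) {
    abort("Scenario target patches fall outside the grid.")
  }
  idx <- cell_index(ls, tp$row, tp$col)
  out <- ls
  out$agc[idx] <- spec$new_agc
  bp <- attr(ls, "breakpoints"); dt <- attr(ls, "density_table")
  out$habitat[idx] <- classify_habitat(spec$new_agc, bp)
  out$capacity[idx] <- carrying_capacity(spec$new_agc, dt, bp)
  out
}

#' Fragment areas of the Taita Hills reference fragment set
#'
#' The 19 printed montane-forest fragment areas (hectares) of the reference
#' fragment table bundled as [taita_fragments]; used as the default fragment
#' size distribution of the synthetic landscape generator.
#'
#' @return Integer vector of areas in hectares, descending.
#' @export
taita_fragment_areas <- function() {
  c(180L, 145L, 91L, 26L, 22L, 15L, 14L, 8L, 7L, 5L, 4L, 4L, 4L, 3L, 2L,
    1L, 1L, 1L, 1L)
}

#' Default AGC levels of the synthetic landscape generator
#'
#' Four levels: the low-AGC `matrix` (cropland), the intermediate `edge`
#' transition ring around each fragment (bushland), and the fragment levels
#' `contact` and `forest`, both defaulting to 95 Mg C ha^-1 - just above
#' the 90 forest threshold and inside both founder tolerance bands. Two
#' deliberate symmetries drive mixing, emulating the connected
#' near-optimum movement chains of a continuously varying real map: all
#' fragment cells are equidistant from the montane specialist's optimum
#' (so a fragment is one roaming neighbourhood under the greedy rule), and
#' matrix (5) and fragment (95) cells are equidistant from the lowland
#' species' optimum (50), so its matrix random walks can percolate into
#' fragment edges wherever the patchy transition ring leaves gaps. Set
#' `forest` higher (e.g. 265, also equidistant from 180) for fragments
#' with a dense interior core that only the pure specialist tolerates.
#'
#' @return Named numeric vector.
#' @export
default_agc_levels <- function() {
  c(matrix = 5, edge = 60, contact = 95, forest = 95)
}

# compact roughly-square blob of `area` cells, as 0-based (dr, dc) offsets
blob_offsets <- function(area) {
  w <- ceiling(sqrt(area))
  h <- ceiling(area / w)
  cells <- expand.grid(dr = 0:(h - 1), dc = 0:(w - 1))
  cells <- cells[order(cells$dr, cells$dc), ]
  cells[seq_len(area), , drop = FALSE]
}

# straight 8-connected line of cells between two points (inclusive)
bridge_cells <- function(r1, c1, r2, c2) {
  n <- max(abs(r2 - r1), abs(c2 - c1))
  if (n == 0) return(tibble::tibble(row = r1, col = c1))
  t <- seq(0, 1, length.out = n + 1)
  tibble::tibble(row = round(r1 + t * (r2 - r1)),
                 col = round(c1 + t * (c2 - c1)))
}

#' Generate a synthetic fragmented AGC landscape
#'
#' Emulates the structure of the Taita Hills AGC map: a low-AGC matrix
#' containing compact montane-forest fragments of the requested areas, each
#' with an intermediate-AGC transition ring at its edge. A fragment's
#' outermost forest cells take the `contact` AGC level so that a hybrid
#' contact zone exists along fragment edges, as on the real map where edge
#' forest sits just above the 90 Mg C ha^-1 threshold.
#'
#' Alongside the grid, the generator derives one scenario of each kind and
#' stores them (with the ground-truth fragment table) as attributes:
#' * `edge_depletion`: contact-ring cells of the three largest fragments to
#'   woodland AGC (20);
#' * `fragment_clearing`: the `n_clear` smallest fragments to 20;
#' * `corridor_planting`: a one-patch-wide bridge between the two largest
#'   fragments at AGC 100;
#' * `plantation_conversion`: a new `plantation_area`-ha forest block (AGC
#'   100) in the matrix;
#' * `control`: no change.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param fragment_areas Fragment areas in hectares (1 patch = 1 ha).
#' @param edge_width Width (patches) of the transition ring.
#' @param contact_width Width (patches) of a fragment's contact edge: the
#'   outermost forest cells carrying the `contact` AGC level (only visible
#'   when `forest` and `contact` levels differ).
#' @param edge_coverage Fraction of ring cells actually holding the edge AGC
#'   level; the rest stay matrix, leaving gaps where matrix touches the
#'   fragment's contact cells directly (real transition zones are patchy,
#'   and the gaps let lowland birds percolate up to the forest edge).
#' @param agc_levels Named vector with entries `matrix`, `edge`, `contact`,
#'   `forest`; see [default_agc_levels()].
#' @param seed Optional integer; fixes placement (RNG state is restored).
#' @param n_clear Number of smallest fragments removed by the
#'   `fragment_clearing` scenario.
#' @param plantation_area Area (ha) of the `plantation_conversion` block.
#' @param max_tries Placement retries per fragment before giving up.
#' @inheritParams landscape
#' @return A `zos_landscape` with extra attributes `fragments` (ground-truth
#'   fragment table in the [identify_fragments()] format) and `scenarios`
#'   (named list of `zos_scenario`).
#' @export
generate_landscape <- function(n_rows = 150, n_cols = 150,
                               fragment_areas = taita_fragment_areas(),
                               edge_width = 1, edge_coverage = 0.25,
                               contact_width = 2,
                               agc_levels = default_agc_levels(),
                               seed = NULL, n_clear = 4,
                               plantation_area = 294, max_tries = 2000,
                               density_table = default_density_table(),
                               breakpoints = default_breakpoints()) {
  stopifnot(all(c("matrix", "edge", "contact", "forest") %in% names(agc_levels)))
  if (!is.null(seed)) withr::local_seed(seed)
  areas <- sort(as.integer(fragment_areas), decreasing = TRUE)
  agc <- matrix(agc_levels[["matrix"]], n_rows, n_cols)
  # reserved marks blob cells plus a separation halo so fragments stay
  # disjoint under 8-connectivity and rings do not touch foreign blobs
  reserved <- matrix(FALSE, n_rows, n_cols)
  halo <- edge_width + 2L

  place_block <- function(offs, agc_val) {
    h <- max(offs$dr) + 1L; w <- max(offs$dc) + 1L
    for (try in seq_len(max_tries)) {
      r0 <- sample.int(n_rows - h + 1L, 1L)
      c0 <- sample.int(n_cols - w + 1L, 1L)
      rows <- r0 + offs$dr; cols <- c0 + offs$dc
      hr <- max(1L, r0 - halo):min(n_rows, r0 + h - 1L + halo)
      hc <- max(1L, c0 - halo):min(n_cols, c0 + w - 1L + halo)
      if (any(reserved[hr, hc])) next
      reserved[cbind(rows, cols)] <<- TRUE
      return(list(rows = rows, cols = cols))
    }
    abort("Could not place all fragments; grid too small for the requested areas.")
  }

  blobs <- vector("list", length(areas))
  for (i in seq_along(areas)) {
    offs <- blob_offsets(areas[i])
    blobs[[i]] <- place_block(offs, agc_levels[["forest"]])
  }

  blob_mask <- matrix(FALSE, n_rows, n_cols)
  for (b in blobs) blob_mask[cbind(b$rows, b$cols)] <- TRUE

  # edge rings: within Chebyshev distance edge_width of a blob, not a blob
  ring_of <- function(mask, width) {
    out <- mask
    for (w in seq_len(width)) {
      grown <- out
      grown[-1, ] <- grown[-1, ] | out[-nrow(out), ]
      grown[-nrow(out), ] <- grown[-nrow(out), ] | out[-1, ]
      grown[, -1] <- grown[, -1] | out[, -ncol(out)]
      grown[, -ncol(out)] <- grown[, -ncol(out)] | out[, -1]
      grown[-1, -1] <- grown[-1, -1] | out[-nrow(out), -ncol(out)]
      grown[-1, -ncol(out)] <- grown[-1, -ncol(out)] | out[-nrow(out), -1]
      grown[-nrow(out), -1] <- grown[-nrow(out), -1] | out[-1, -ncol(out)]
      grown[-nrow(out), -ncol(out)] <- grown[-nrow(out), -ncol(out)] | out[-1, -1]
      out <- grown
    }
    out & !mask
  }
  if (edge_width > 0) {
    ring <- ring_of(blob_mask, edge_width)
    ring[ring] <- runif(sum(ring)) < edge_coverage
    agc[ring] <- agc_levels[["edge"]]
  }
  agc[blob_mask] <- agc_levels[["forest"]]
  # a blob's outermost cells (within contact_width of a non-blob cell)
  # become contact cells
  interior <- blob_mask & !ring_of(!blob_mask, contact_width)
  perim_mask <- blob_mask & !interior
  agc[perim_mask] <- agc_levels[["contact"]]

  ls <- landscape(agc, density_table, breakpoints)

  # ground truth fragments, largest first (placement order)
  gt <- purrr::imap(blobs, function(b, i) {
    tibble::tibble(fragment = i, area_ha = length(b$rows),
                   centroid_row = mean(b$rows), centroid_col = mean(b$cols),
                   patches = list(tibble::tibble(row = b$rows, col = b$cols) |>
                                    dplyr::arrange(.data$row, .data$col)))
  }) |> purrr::list_rbind()

  perim_cells <- function(b) {
    keep <- perim_mask[cbind(b$rows, b$cols)]
    tibble::tibble(row = b$rows[keep], col = b$cols[keep])
  }
  edge_targets <- purrr::map(blobs[seq_len(min(3, length(blobs)))], perim_cells) |>
    purrr::list_rbind()
  small_idx <- utils::tail(seq_along(blobs), min(n_clear, length(blobs)))
  clear_targets <- purrr::map(blobs[small_idx], function(b) {
    tibble::tibble(row = b$rows, col = b$cols)
  }) |> purrr::list_rbind()
  corridor <- if (length(blobs) >= 2) {
    br <- bridge_cells(round(gt$centroid_row[1]), round(gt$centroid_col[1]),
                       round(gt$centroid_row[2]), round(gt$centroid_col[2]))
    dplyr::anti_join(br, dplyr::bind_rows(purrr::map(blobs, function(b) {
      tibble::tibble(row = b$rows, col = b$cols)
    })), by = c("row", "col")) |> dplyr::distinct()
  } else tibble::tibble(row = integer(), col = integer())
  plant_offs <- blob_offsets(plantation_area)
  plant <- place_block(plant_offs, 100)
  plant_targets <- tibble::tibble(row = plant$rows, col = plant$cols)

  scenarios <- list(
    control = scenario_spec("control"),
    edge_depletion = scenario_spec("edge_depletion", edge_targets),
    fragment_clearing = scenario_spec("fragment_clearing", clear_targets),
    corridor_planting = scenario_spec("corridor_planting", corridor),
    plantation_conversion = scenario_spec("plantation_conversion", plant_targets)
  )
  attr(ls, "fragments") <- gt
  attr(ls, "scenarios") <- scenarios
  ls
}
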
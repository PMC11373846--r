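#' Write a landscape to a directory of ASCII grid layers
#'
#' One file per layer, all sharing the same geotransform: covariates as
#' `<name>.asc`, logical masks as `mask_<name>.asc` (0/1), categorical
#' masks as `mask_<name>.asc` (integer codes) with a `<name>_levels.csv`
#' sidecar mapping codes to labels.
#'
#' @param landscape A [landscape()].
#' @param dir Output directory (created if needed).
#' @export
write_landscape <- function(landscape, dir) {
  stopifnot(inherits(landscape, "bear_landscape"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- landscape$grid
  for (nm in covariate_names())
    write_ascii_grid(landscape$covariates[[nm]], g,
                     file.path(dir, paste0(nm, ".asc")))
  for (nm in names(landscape$masks)) {
    m <- landscape$masks[[nm]]
    path <- file.path(dir, paste0("mask_", nm, ".asc"))
    if (is.logical(m)) {
      write_ascii_grid(m * 1, g, path)
    } else {
      levels <- sort(unique(as.vector(m[!is.na(m)])))
      codes <- matrix(match(m, levels), nrow(m), ncol(m))
      write_ascii_grid(codes, g, path)
      write.csv(data.frame(code = seq_along(levels), label = levels),
                file.path(dir, paste0(nm, "_levels.csv")), row.names = FALSE)
    }
  }
  invisible(dir)
}

#' Read a landscape from a directory of ASCII grid layers
#'
#' Inverse of [write_landscape()]. All layers must share an identical
#' geotransform.
#'
#' @param dir Directory holding the layer files.
#' @return A [landscape()].
#' @export
read_landscape <- function(dir) {
  covs <- list()
  grid <- NULL
  for (nm in covariate_names()) {
    lay <- read_ascii_grid(file.path(dir, paste0(nm, ".asc")))
    if (is.null(grid)) grid <- lay$grid
    else if (!same_grid(grid, lay$grid)) stop("layer '", nm, "' has a different geotransform")
    covs[[nm]] <- lay$values
  }
  masks <- list()
  for (f in list.files(dir, pattern = "^mask_.*\\.asc$")) {
    nm <- sub("^mask_", "", sub("\\.asc$", "", f))
    lay <- read_ascii_grid(file.path(dir, f))
    if (!same_grid(grid, lay$grid)) stop("mask '", nm, "' has a different geotransform")
    levels_file <- file.path(dir, paste0(nm, "_levels.csv"))
    if (file.exists(levels_file)) {
      lv <- read.csv(levels_file, stringsAsFactors = FALSE)
      m <- matrix(lv$label[match(lay$values, lv$code)],
                  grid$nrows, grid$ncols)
    } else {
      m <- !is.na(lay$values) & lay$values != 0
    }
    masks[[nm]] <- m
  }
  landscape(grid, covs, masks)
}
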
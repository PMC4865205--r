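# Segmentation error metric, dataset evaluation against ground-truth masks,
# and the training-set grid search for the per-sensor parameters (C, gamma, t).

#' Pixelwise segmentation error
#'
#' Confusion counts between an estimated and a ground-truth mask:
#' \eqn{M_f} foreground pixels estimated as background (missed foreground),
#' \eqn{M_b} background pixels estimated as foreground, and the per-image
#' error
#' \deqn{\mathrm{Err} = \frac{M_f + M_b}{N_1 \times N_2}}
#' with \eqn{N_1 \times N_2} the image size in pixels.
#'
#' @param estimated,truth logical matrices of identical dimension
#'   (\code{TRUE} = foreground).
#' @return a list with components \code{Mf}, \code{Mb}, \code{N1} (width),
#'   \code{N2} (height) and \code{err}.
#' @examples
#' a <- matrix(FALSE, 10, 10); a[3:7, 3:7] <- TRUE
#' errorRate(a, a)$err  # 0
#' @export
errorRate <- function(estimated, truth) {
  stopifnot(is.matrix(estimated), is.matrix(truth))
  if (!all(dim(estimated) == dim(truth)))
    stop("mask dimensions differ")
  estimated <- estimated & !is.na(estimated)
  truth <- truth & !is.na(truth)
  Mf <- sum(truth & !estimated)
  Mb <- sum(!truth & estimated)
  list(Mf = Mf, Mb = Mb, N1 = ncol(truth), N2 = nrow(truth),
       err = (Mf + Mb) / length(truth))
}

#' Read / write a dataset manifest
#'
#' A manifest is a two-column tab-separated text file listing image and
#' ground-truth mask paths, one pair per line, no header. Relative paths are
#' resolved against the manifest's directory.
#'
#' @param path manifest file path.
#' @return \code{readManifest}: a data.frame with columns \code{image} and
#'   \code{mask} (absolute paths).
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("image", "mask"))
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                            file.path(base, p))
  data.frame(image = fix(df$image), mask = fix(df$mask),
             stringsAsFactors = FALSE)
}

#' @rdname readManifest
#' @param pairs data.frame with columns \code{image} and \code{mask}.
#' @export
writeManifest <- function(pairs, path) {
  utils::write.table(pairs[, c("image", "mask")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Evaluate segmentation over a dataset
#'
#' Segments every image of a manifest with the given parameters, compares
#' each result with its ground-truth mask, and returns per-image confusion
#' counts plus the unweighted mean of the per-image errors (each image counts
#' equally regardless of its size). Unreadable or mismatched pairs are
#' recorded as failures, excluded from the mean, and reported with a warning.
#'
#' @param manifest a manifest path or the data.frame returned by
#'   [readManifest()].
#' @param params a [FDBParams-class] object.
#' @param reportFile optional path; when given, the per-image table plus a
#'   summary row is written there as CSV.
#' @return a list with \code{results} (data.frame with columns image, Mf, Mb,
#'   N1, N2, err, ok) and \code{meanErr}.
#' @export
evaluateDataset <- function(manifest, params, reportFile = NULL) {
  if (is.character(manifest)) manifest <- readManifest(manifest)
  stopifnot(is(params, "FDBParams"), nrow(manifest) >= 1L)
  rows <- vector("list", nrow(manifest))
  banks <- new.env(parent = emptyenv())  # filter banks cached per image size
  for (i in seq_len(nrow(manifest))) {
    res <- tryCatch({
      img <- readGrayImage(manifest$image[i])
      truth <- readMask(manifest$mask[i])
      if (!all(dim(img) == dim(truth)))
        stop("image and mask dimensions differ")
      key <- paste(dim(img) + 2L * params@pad, collapse = "x")
      if (is.null(banks[[key]]))
        banks[[key]] <- dhbbFilterBank(dim(img) + 2L * params@pad, params)
      er <- errorRate(segmentFingerprint(img, params, bank = banks[[key]]),
                      truth)
      data.frame(image = manifest$image[i], Mf = er$Mf, Mb = er$Mb,
                 N1 = er$N1, N2 = er$N2, err = er$err, ok = TRUE,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("skipping '%s': %s", manifest$image[i],
                      conditionMessage(e)), call. = FALSE)
      data.frame(image = manifest$image[i], Mf = NA_integer_,
                 Mb = NA_integer_, N1 = NA_integer_, N2 = NA_integer_,
                 err = NA_real_, ok = FALSE, stringsAsFactors = FALSE)
    })
    rows[[i]] <- res
  }
  results <- do.call(rbind, rows)
  meanErr <- mean(results$err[results$ok])
  if (!is.null(reportFile)) {
    out <- results
    out$err <- formatC(out$err, digits = 8, format = "f")
    summary <- data.frame(image = "MEAN", Mf = NA, Mb = NA, N1 = NA, N2 = NA,
                          err = formatC(meanErr, digits = 8, format = "f"),
                          ok = all(results$ok), stringsAsFactors = FALSE)
    utils::write.csv(rbind(out, summary), reportFile, row.names = FALSE)
  }
  list(results = results, meanErr = meanErr)
}

#' Grid search for the per-sensor parameters
#'
#' Exhaustively evaluates every combination of the supplied \code{C},
#' \code{gamma} and \code{t} values on a training manifest (all other
#' parameters fixed at their values in \code{fixed}) and returns the
#' combination with the smallest mean error. Ties are broken towards the
#' lexicographically smallest \code{(C, gamma, t)}. The default grid
#' (\code{C} = 0.03..0.09 by 0.01, \code{gamma} = 1..4, \code{t} = 4..7)
#' spans the per-sensor values trained for the FVC databases.
#'
#' @param manifest training manifest path or data.frame.
#' @param Cgrid,gammaGrid,tGrid numeric vectors of candidate values.
#' @param fixed a [FDBParams-class] object supplying the non-searched
#'   parameters.
#' @return a list with \code{params} (the selected [FDBParams-class]),
#'   \code{trainErr}, and \code{table} (the full grid with mean errors).
#' @export
gridSearchParams <- function(manifest,
                             Cgrid = seq(0.03, 0.09, by = 0.01),
                             gammaGrid = 1:4, tGrid = 4:7,
                             fixed = fdbParams()) {
  if (is.character(manifest)) manifest <- readManifest(manifest)
  stopifnot(nrow(manifest) >= 1L,
            length(Cgrid) >= 1L, length(gammaGrid) >= 1L,
            length(tGrid) >= 1L)
  grid <- expand.grid(C = sort(Cgrid), gamma = sort(gammaGrid),
                      t = sort(tGrid), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$C, grid$gamma, grid$t), , drop = FALSE]
  grid$meanErr <- NA_real_
  for (i in seq_len(nrow(grid))) {
    p <- fdbParams(C = grid$C[i], n = fixed@n, L = fixed@L,
                   gamma = grid$gamma[i], omegaLow = fixed@omegaLow,
                   omegaHigh = fixed@omegaHigh, s = fixed@s, t = grid$t[i],
                   b = fixed@b, pad = fixed@pad, variant = fixed@variant)
    grid$meanErr[i] <- suppressWarnings(evaluateDataset(manifest, p)$meanErr)
  }
  best <- which.min(grid$meanErr)   # first minimum = lexicographic tie-break
  params <- fdbParams(C = grid$C[best], n = fixed@n, L = fixed@L,
                      gamma = grid$gamma[best], omegaLow = fixed@omegaLow,
                      omegaHigh = fixed@omegaHigh, s = fixed@s,
                      t = grid$t[best], b = fixed@b, pad = fixed@pad,
                      variant = fixed@variant)
  list(params = params, trainErr = grid$meanErr[best], table = grid)
}
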
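#' Specify a synthetic retinal phantom
#'
#' Phantoms emulate the image properties the pipeline exploits: OCT
#' B-scans are stacked horizontal reflectivity bands with a parabolic
#' foveal dip, multiplicative speckle and (for ME) hypo-reflective
#' intraretinal fluid blobs plus central retinal thickening; fundus
#' phantoms are a circular field of view with a bright optic disc, a
#' darker macula, a recursive dark vessel tree and (for ME) bright hard
#' exudate blobs near the macula. The seed fully determines the output.
#'
#' @param modality \code{"oct"} or \code{"fundus"}.
#' @param label \code{"healthy"} or \code{"me"}.
#' @param rows,cols phantom shape; defaults 496 x 512 (OCT) and
#'   576 x 720 (fundus), typical acquisition sizes.
#' @param nLayers number of OCT boundary curves (including ILM and RPE,
#'   at most 9).
#' @param speckle multiplicative speckle level in [0, 1) (OCT; fundus uses
#'   a quarter of it). Intensities are multiplied by
#'   \code{1 + speckle * U(-1, 1)}.
#' @param fluidBlobs ME OCT only: number of fluid blobs, or NULL to draw
#'   1-4 from the seed. Must be 0/NULL for healthy phantoms.
#' @param vesselDepth recursion depth of the fundus vessel tree.
#' @param exudateCount ME fundus only: number of exudate blobs, or NULL to
#'   draw 6-18 from the seed.
#' @param annotationRows add bright acquisition annotations in the first
#'   and last 50 rows (OCT).
#' @param degraded add a saturated degraded block at the scan margin.
#' @param umLateral lateral micrometers per pixel (default 11.6 for OCT,
#'   so 500 um is about 43 px).
#' @param seed RNG seed; the same spec always renders the same phantom.
#' @return A list of class \code{"PhantomSpec"}.
#' @export
phantomSpec <- function(modality = c("oct", "fundus"),
                        label = c("healthy", "me"),
                        rows = NULL, cols = NULL, nLayers = 9L,
                        speckle = 0.2, fluidBlobs = NULL,
                        vesselDepth = 5L, exudateCount = NULL,
                        annotationRows = FALSE, degraded = FALSE,
                        umLateral = NULL, seed = 1L) {
  modality <- match.arg(modality)
  label <- match.arg(label)
  if (is.null(rows)) rows <- if (modality == "oct") 496L else 576L
  if (is.null(cols)) cols <- if (modality == "oct") 512L else 720L
  if (rows < 64L || cols < 64L) stop("phantom too small")
  if (nLayers < 2L || nLayers > 9L) stop("nLayers must be in 2..9")
  if (speckle < 0 || speckle >= 1) stop("speckle must be in [0, 1)")
  if (label == "healthy" && !is.null(fluidBlobs) && fluidBlobs > 0)
    stop("fluid blobs are inconsistent with a healthy phantom")
  if (label == "healthy" && !is.null(exudateCount) && exudateCount > 0)
    stop("exudates are inconsistent with a healthy phantom")
  if (!is.null(fluidBlobs) && (fluidBlobs < 0 || fluidBlobs > 4))
    stop("fluidBlobs must be in 0..4")
  if (is.null(umLateral)) umLateral <- if (modality == "oct") 11.6 else 8.0
  structure(list(modality = modality, label = label, rows = as.integer(rows),
                 cols = as.integer(cols), nLayers = as.integer(nLayers),
                 speckle = speckle, fluidBlobs = fluidBlobs,
                 vesselDepth = as.integer(vesselDepth),
                 exudateCount = exudateCount,
                 annotationRows = annotationRows, degraded = degraded,
                 umLateral = umLateral, seed = as.integer(seed)),
            class = "PhantomSpec")
}

gaussBlur2 <- function(m, sigma) {
  g <- gaussianKernel1D(sigma, 0L)
  correlate2(m, outer(g, g))
}

#' Generate an OCT B-scan phantom with ground truth
#'
#' @param spec a \code{\link{phantomSpec}} with \code{modality = "oct"}.
#' @return A list with elements \code{scan} (a
#'   \linkS4class{RetinalScan}) and \code{truth} (boundaries matrix,
#'   fluid mask, fovea column, label).
#' @examples
#' ph <- generateOCTPhantom(phantomSpec("oct", "me", seed = 5))
#' dim(ph$scan)
#' @export
generateOCTPhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"), spec$modality == "oct")
  withSeed(spec$seed, {
    nr <- spec$rows; nc <- spec$cols
    me <- spec$label == "me"
    foveaCol <- round(nc / 2 + runif(1, -25, 25))
    ilmBase <- round(nr * (if (me) 0.31 else 0.35)) + runif(1, -8, 8)
    dip <- if (me) 22 else 45
    rpeRow <- round(nr * 0.72) + runif(1, -5, 5)
    halfWidth <- nc * 0.14
    dd <- pmax(0, 1 - ((seq_len(nc) - foveaCol) / halfWidth)^2)
    ilm <- ilmBase + dip * dd
    k <- spec$nLayers
    fr <- seq(0, 1, length.out = k)
    B <- t(vapply(fr, function(f) (1 - f) * ilm + f * rpeRow,
                  numeric(nc)))
    # distinct band reflectivities, RPE band brightest
    refl <- c(0.42, 0.68, 0.45, 0.72, 0.40, 0.70, 0.44, 0.85)
    refl <- c(refl[seq_len(max(0, k - 2))], 0.85)[seq_len(k - 1)]
    img <- matrix(0.05, nr, nc)
    rowIdx <- matrix(seq_len(nr), nr, nc)
    for (b in seq_len(k - 1)) {
      top <- matrix(B[b, ], nr, nc, byrow = TRUE)
      bot <- matrix(B[b + 1, ], nr, nc, byrow = TRUE)
      img[rowIdx >= top & rowIdx < bot] <- refl[b]
    }
    fluid <- matrix(0, nr, nc)
    if (me) {
      nBlob <- if (is.null(spec$fluidBlobs)) sample(1:4, 1) else
        spec$fluidBlobs
      centers <- matrix(numeric(0), 0, 4)  # row, col, a (vert), b (horiz)
      tries <- 0L
      while (nrow(centers) < nBlob && tries < 500L) {
        tries <- tries + 1L
        a <- runif(1, 9, 14); b <- runif(1, 11, 18)
        cx <- runif(1, 40 + b, nc - 40 - b)
        lo <- ilm[round(cx)] + a + 8
        hi <- rpeRow - a - 8
        if (lo >= hi) next
        cy <- runif(1, lo, hi)
        if (nrow(centers) > 0 &&
            any(abs(centers[, 2] - cx) < (centers[, 4] + b + 18) &
                abs(centers[, 1] - cy) < (centers[, 3] + a + 12))) next
        centers <- rbind(centers, c(cy, cx, a, b))
      }
      for (q in seq_len(nrow(centers))) {
        cy <- centers[q, 1]; cx <- centers[q, 2]
        a <- centers[q, 3]; b <- centers[q, 4]
        jj <- max(1, floor(cx - b)):min(nc, ceiling(cx + b))
        ii <- max(1, floor(cy - a)):min(nr, ceiling(cy + a))
        el <- outer(((ii - cy) / a)^2, ((jj - cx) / b)^2, "+") <= 1
        sub <- img[ii, jj, drop = FALSE]; sub[el] <- 0.08
        img[ii, jj] <- sub
        fsub <- fluid[ii, jj, drop = FALSE]; fsub[el] <- 1
        fluid[ii, jj] <- fsub
      }
    }
    img <- gaussBlur2(img, 1.2)
    if (spec$speckle > 0)
      img <- img * (1 + spec$speckle * runif(nr * nc, -1, 1))
    if (spec$annotationRows) {
      for (rr in list(8:20, (nr - 19):(nr - 7))) {
        for (s in seq_len(6)) {
          j0 <- sample(10:(nc - 60), 1)
          img[sample(rr, 6), j0:(j0 + sample(20:50, 1))] <- 0.95
        }
      }
    }
    if (spec$degraded) {
      img[1:60, 1:20] <- 1
      img[(nr - 49):nr, (nc - 17):nc] <- 1
    }
    scan <- RetinalScan(clamp01(img), modality = "oct",
                        umPerPixel = c(lateral = spec$umLateral),
                        sourceId = sprintf("oct-phantom-seed%d", spec$seed))
    storage.mode(fluid) <- "integer"   # halves cohort memory
    truth <- list(boundaries = B, ilmIndex = 1L, rpeIndex = k,
                  fluid = fluid, foveaCol = foveaCol, label = spec$label)
    list(scan = scan, truth = truth)
  })
}

# Trace one vessel tree: returns a matrix of (row, col, width) centreline
# points. Rasterization happens once, per width class, in the caller.
traceVesselTree <- function(start, angle, width, depth, fovC, fovR) {
  stack <- list(list(p = start, a = angle, w = width, d = depth))
  pts <- vector("list", 0L)
  while (length(stack)) {
    s <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    p <- s$p; a <- s$a
    nStep <- ceiling(runif(1, 45, 85))
    seg <- matrix(NA_real_, nStep, 3L)
    kept <- 0L
    for (t in seq_len(nStep)) {
      a <- a + runif(1, -0.08, 0.08)
      p <- p + c(sin(a), cos(a))
      if (sqrt(sum((p - fovC)^2)) > fovR - 12) break
      kept <- kept + 1L
      seg[kept, ] <- c(p, s$w)
    }
    if (kept) pts[[length(pts) + 1L]] <- seg[seq_len(kept), , drop = FALSE]
    if (s$d > 1 && sqrt(sum((p - fovC)^2)) <= fovR - 12) {
      da <- runif(1, 0.25, 0.6)
      stack[[length(stack) + 1L]] <-
        list(p = p, a = a + da, w = max(1.2, s$w * 0.78), d = s$d - 1L)
      stack[[length(stack) + 1L]] <-
        list(p = p, a = a - da, w = max(1.2, s$w * 0.78), d = s$d - 1L)
    }
  }
  if (!length(pts)) matrix(numeric(0), 0, 3) else do.call(rbind, pts)
}

# Rasterize centreline points into a binary mask by dilating per width
# class (odd brush diameters).
rasterizeVessels <- function(pts, nr, nc) {
  mask <- matrix(0, nr, nc)
  if (!nrow(pts)) return(mask)
  ij <- cbind(pmin(pmax(round(pts[, 1]), 1L), nr),
              pmin(pmax(round(pts[, 2]), 1L), nc))
  wclass <- pmax(1L, 2L * as.integer(round(pts[, 3] / 2)) + 1L)
  for (w in sort(unique(wclass))) {
    cm <- matrix(0, nr, nc)
    cm[ij[wclass == w, , drop = FALSE]] <- 1
    if (w > 1L)
      cm <- EBImage::imageData(EBImage::dilate(EBImage::Image(cm),
              EBImage::makeBrush(w, "disc")))
    mask[cm > 0] <- 1
  }
  mask
}

#' Generate a fundus photograph phantom with ground truth
#'
#' @param spec a \code{\link{phantomSpec}} with \code{modality = "fundus"}.
#' @return A list with elements \code{scan} (3-channel
#'   \linkS4class{RetinalScan}) and \code{truth} (vessel and exudate
#'   masks, optic disc, macula centre, label).
#' @export
generateFundusPhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"), spec$modality == "fundus")
  withSeed(spec$seed, {
    nr <- spec$rows; nc <- spec$cols
    me <- spec$label == "me"
    fovC <- c(nr / 2, nc / 2)
    fovR <- min(nr, nc) * 0.45
    ii <- matrix(seq_len(nr), nr, nc)
    jj <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    d2fov <- (ii - fovC[1])^2 + (jj - fovC[2])^2
    fov <- d2fov <= fovR^2
    img <- matrix(0, nr, nc)
    img[fov] <- 0.5
    # optic disc on the nasal side, macula on the temporal side
    discC <- c(fovC[1] + runif(1, -15, 15), fovC[2] + fovR * 0.62 +
                 runif(1, -10, 10))
    discR <- 38
    macC <- c(fovC[1] + runif(1, -10, 10), fovC[2] - fovR * 0.52 +
                runif(1, -10, 10))
    d2mac <- (ii - macC[1])^2 + (jj - macC[2])^2
    img <- img - 0.17 * exp(-d2mac / (2 * (55 / 1.2)^2)) * fov
    d2disc <- (ii - discC[1])^2 + (jj - discC[2])^2
    img[d2disc <= discR^2] <- 0.88
    # vessel tree out of the disc
    nTrunk <- 6L
    angles <- seq(0, 2 * pi, length.out = nTrunk + 1L)[-1] +
      runif(nTrunk, -0.2, 0.2)
    pts <- if (spec$vesselDepth >= 1L)
      do.call(rbind, lapply(angles, function(a)
        traceVesselTree(discC, a, 5, spec$vesselDepth, fovC, fovR)))
    else matrix(numeric(0), 0, 3)
    vmask <- rasterizeVessels(pts, nr, nc)
    vmask[d2disc <= discR^2] <- 0
    vmask[!fov] <- 0
    img[vmask > 0] <- pmax(img[vmask > 0] - 0.22, 0.05)
    emask <- matrix(0, nr, nc)
    if (me) {
      nEx <- if (is.null(spec$exudateCount)) sample(6:18, 1) else
        spec$exudateCount
      vDil <- EBImage::imageData(EBImage::dilate(EBImage::Image(vmask),
               EBImage::makeBrush(7L, "disc"))) > 0
      placed <- 0L; tries <- 0L
      while (placed < nEx && tries < 2000L) {
        tries <- tries + 1L
        r <- runif(1, 3, 8)
        cy <- macC[1] + runif(1, -114, 114)
        cx <- macC[2] + runif(1, -114, 114)
        if (sqrt((cy - macC[1])^2 + (cx - macC[2])^2) > 114) next
        if ((cy - fovC[1])^2 + (cx - fovC[2])^2 > (fovR - 15)^2) next
        ci <- round(cy); cj <- round(cx)
        box <- vDil[max(1, ci - ceiling(r) - 1):min(nr, ci + ceiling(r) + 1),
                    max(1, cj - ceiling(r) - 1):min(nc, cj + ceiling(r) + 1)]
        if (any(box)) next
        emask <- stampDisc(emask, cy, cx, r)
        placed <- placed + 1L
      }
      img[emask > 0] <- 0.82
    }
    img <- gaussBlur2(img, 1.0)
    img[!fov] <- 0
    if (spec$speckle > 0)
      img <- img * (1 + spec$speckle / 4 * runif(nr * nc, -1, 1))
    img <- clamp01(img)
    px <- array(0, c(nr, nc, 3))
    px[, , 1] <- clamp01(img * 1.25 + 0.06 * fov)
    px[, , 2] <- img
    px[, , 3] <- img * 0.45
    scan <- RetinalScan(px, modality = "fundus",
                        umPerPixel = c(lateral = spec$umLateral),
                        sourceId = sprintf("fundus-phantom-seed%d",
                                           spec$seed))
    storage.mode(vmask) <- "integer"
    storage.mode(emask) <- "integer"
    truth <- list(vessels = vmask, exudates = emask,
                  opticDisc = c(cx = discC[2], cy = discC[1], r = discR),
                  macula = c(cx = macC[2], cy = macC[1]),
                  label = spec$label)
    list(scan = scan, truth = truth)
  })
}

#' Generate a paired OCT + fundus phantom cohort
#'
#' Each subject receives one OCT and one fundus phantom sharing a label;
#' \code{round(n * prevalence)} subjects are ME, the rest healthy. Labels
#' are assigned to train/validation splits stratified by class.
#'
#' @param n number of subjects.
#' @param prevalence fraction of ME subjects in [0, 1].
#' @param seed cohort seed; per-subject phantom seeds are derived from it.
#' @param dir optional directory: when given, scans, truth masks and the
#'   manifest CSV are written there.
#' @param trainFrac fraction of subjects in the training split.
#' @param speckle speckle level passed to every phantom.
#' @return A list of class \code{"retfuseCohort"} with \code{subjects}
#'   (per-subject scans and truths) and \code{manifest} (a data.frame in
#'   the manifest schema).
#' @export
generateCohort <- function(n, prevalence = 0.5, seed = 1L, dir = NULL,
                           trainFrac = 0.7, speckle = 0.2) {
  if (n < 1) stop("n must be at least 1")
  if (prevalence < 0 || prevalence > 1) stop("prevalence must be in [0, 1]")
  nME <- round(n * prevalence)
  labels <- c(rep("me", nME), rep("healthy", n - nME))
  split <- character(n)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    nTrain <- round(length(idx) * trainFrac)
    split[idx] <- c(rep("train", nTrain),
                    rep("validation", length(idx) - nTrain))
  }
  subjects <- vector("list", n)
  rows <- list()
  for (i in seq_len(n)) {
    sSeed <- as.integer((as.numeric(seed) * 7919 + i * 104729) %%
                          2147483647)
    oct <- generateOCTPhantom(phantomSpec("oct", labels[i],
                                          speckle = speckle, seed = sSeed))
    fun <- generateFundusPhantom(phantomSpec("fundus", labels[i],
                                             speckle = speckle,
                                             seed = sSeed + 1L))
    octPath <- sprintf("subj%04d_oct.png", i)
    funPath <- sprintf("subj%04d_fundus.png", i)
    subjects[[i]] <- list(id = sprintf("subj%04d", i), label = labels[i],
                          split = split[i], oct = oct$scan,
                          octTruth = oct$truth, fundus = fun$scan,
                          fundusTruth = fun$truth)
    rows[[length(rows) + 1L]] <-
      data.frame(path = c(octPath, funPath),
                 modality = c("oct", "fundus"),
                 label = labels[i], split = split[i],
                 stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(n)) {
      s <- subjects[[i]]
      writeScan(file.path(dir, sprintf("subj%04d_oct.png", i)), s$oct)
      writeScan(file.path(dir, sprintf("subj%04d_fundus.png", i)),
                s$fundus)
      writeMask(file.path(dir, sprintf("subj%04d_fluid_truth.png", i)),
                s$octTruth$fluid)
      writeMask(file.path(dir, sprintf("subj%04d_vessel_truth.png", i)),
                s$fundusTruth$vessels)
      writeMask(file.path(dir, sprintf("subj%04d_exudate_truth.png", i)),
                s$fundusTruth$exudates)
    }
    manifest$path <- file.path(dir, manifest$path)
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  structure(list(subjects = subjects, manifest = manifest, seed = seed),
            class = "retfuseCohort")
}
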
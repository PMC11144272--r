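# Grayscale TIFF/PNG image and multi-page TIFF volume I/O. Volume voxel
# sizes travel in a sidecar JSON file next to the TIFF (the installed tiff
# bindings expose no description tag).

#' Read a 2D grayscale image
#'
#' Reads 8/16-bit grayscale TIFF or PNG. RGB(A) inputs are converted to
#' grayscale by channel averaging with a warning.
#'
#' @param path file path (`.tif`, `.tiff` or `.png`).
#' @return numeric matrix in \[0, 1\].
#' @export
readImage2D <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(img)) == 3) {
    warning("multi-channel image ", path, " converted to grayscale")
    img <- apply(img[, , seq_len(min(3, dim(img)[3])), drop = FALSE],
                 c(1, 2), mean)
  }
  img
}

#' Write a 2D grayscale image
#'
#' @param image numeric matrix in \[0, 1\].
#' @param path output path (`.tif`/`.tiff` or `.png`).
#' @param bitsPerSample bit depth for TIFF output: 8, 16 (default) or 32
#'   (float, used for uncertainty maps).
#' @export
writeImage2D <- function(image, path, bitsPerSample = 16L) {
  if (!bitsPerSample %in% c(8L, 16L, 32L))
    stop("unsupported bit depth: ", bitsPerSample)
  ext <- tolower(tools::file_ext(path))
  img <- clamp01(image)
  switch(ext,
    tif = , tiff = tiff::writeTIFF(img, path,
                                   bits.per.sample = as.integer(bitsPerSample),
                                   compression = "none"),
    png = png::writePNG(img, path),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}

volumeMetaPath <- function(path) paste0(path, ".meta.json")

#' Read a volume from multi-page TIFF
#'
#' Pages become axial (z) layers, so the array is indexed (z, y, x). Voxel
#' sizes are recovered from the sidecar `<path>.meta.json`; when absent,
#' (1, 1, 1) is assumed with a warning.
#'
#' @param path multi-page TIFF path.
#' @return an [EMVolume-class].
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("no such volume file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  vol <- array(0, c(length(pages), d[1], d[2]))
  for (z in seq_along(pages)) vol[z, , ] <- pages[[z]]
  mp <- volumeMetaPath(path)
  vs <- if (file.exists(mp)) {
    as.numeric(jsonlite::read_json(mp, simplifyVector = TRUE)$voxel_size_nm)
  } else {
    warning("no voxel-size metadata for ", path, "; assuming (1, 1, 1) nm")
    c(1, 1, 1)
  }
  EMVolume(vol, voxelSize = vs)
}

#' Write a volume as multi-page TIFF with voxel-size metadata
#'
#' @param volume an [EMVolume-class].
#' @param path output TIFF path; `<path>.meta.json` records
#'   `voxel_size_nm` (z, y, x).
#' @param bitsPerSample bit depth (default 16).
#' @export
writeVolume <- function(volume, path, bitsPerSample = 16L) {
  stopifnot(is(volume, "EMVolume"))
  pages <- lapply(seq_len(nLayers(volume)),
                  function(z) clamp01(volume@data[z, , ]))
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bitsPerSample),
                  compression = "none")
  jsonlite::write_json(list(voxel_size_nm = voxelSize(volume)),
                       volumeMetaPath(path), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Write a paired noisy/clean dataset to disk
#'
#' Writes `clean_####.tif` / `noisy_####.tif` pairs plus a `manifest.tsv`
#' recording pairing, dwell times and (when supplied) the planted drift
#' transform of each noisy acquisition.
#'
#' @param dir output directory (created if needed).
#' @param cleanList,noisyList paired lists of matrices.
#' @param dwell numeric dwell value(s) of the noisy acquisitions.
#' @param homographies optional list of 3x3 planted homographies.
#' @return the manifest as a data.frame, invisibly.
#' @export
writePairedDataset <- function(dir, cleanList, noisyList, dwell = NA,
                               homographies = NULL) {
  stopifnot(length(cleanList) == length(noisyList))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dwell <- rep_len(dwell, length(cleanList))
  rows <- lapply(seq_along(cleanList), function(i) {
    cf <- sprintf("clean_%04d.tif", i)
    nf <- sprintf("noisy_%04d.tif", i)
    writeImage2D(cleanList[[i]], file.path(dir, cf))
    writeImage2D(noisyList[[i]], file.path(dir, nf))
    H <- if (is.null(homographies)) diag(3) else homographies[[i]]
    data.frame(pair = i, clean = cf, noisy = nf, dwell = dwell[i],
               t(as.vector(t(H))))
  })
  manifest <- do.call(rbind, rows)
  names(manifest) <- c("pair", "clean", "noisy", "dwell", paste0("h", 1:9))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

readPairedDataset <- function(dir) {
  mf <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf)) stop("no manifest.tsv in ", dir)
  manifest <- utils::read.table(mf, sep = "\t", header = TRUE)
  list(
    manifest = manifest,
    clean = lapply(manifest$clean, function(f) readImage2D(file.path(dir, f))),
    noisy = lapply(manifest$noisy, function(f) readImage2D(file.path(dir, f)))
  )
}

#' Save / load a trained network checkpoint
#'
#' Checkpoints bundle the network (parameters, group manifest, config) and
#' the noise-schedule settings, so inference is reproducible from the file
#' alone.
#'
#' @param net a `DiffusionNet`.
#' @param schedule the [NoiseSchedule-class] it was trained with.
#' @param path output `.rds` path.
#' @export
saveCheckpoint <- function(net, schedule, path) {
  net$opt <- NULL
  saveRDS(list(net = net, Tsteps = schedule@Tsteps,
               beta = schedule@beta), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @return `loadCheckpoint` returns `list(net, schedule)`.
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("no such checkpoint: ", path)
  ck <- readRDS(path)
  sch <- new("NoiseSchedule", Tsteps = ck$Tsteps, beta = ck$beta,
             alpha = 1 - ck$beta, alphaBar = cumprod(1 - ck$beta),
             sigma2 = ck$beta)
  list(net = ck$net, schedule = sch)
}
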
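#' Write a volume to disk as PNG slices or a NIfTI pair
#'
#' PNG format writes one 8-bit grayscale image and two mask files per
#' slice, with zero-padded zero-based indices, plus a \code{manifest.csv}
#' pairing them. NIfTI format writes one 3D image file and one combined
#' label file using labels {0 = background, 1 = liver, 2 = tumor} (tumor
#' overrides liver), the single-segmentation-volume convention of public
#' liver-tumor CT datasets. Masks round-trip exactly; images round-trip
#' within 8-bit quantization for PNG and exactly for NIfTI.
#'
#' @param volume a \linkS4class{VolumePair}
#' @param directory output directory (created if missing)
#' @param format \code{"png"} or \code{"nifti"}
#' @return the manifest as a data.frame, invisibly (also written as
#'   \code{manifest.csv} in \code{directory})
#' @seealso \code{\link{readDataset}}
#' @export
writeDataset <- function(volume, directory, format = c("png", "nifti")) {
  stopifnot(is(volume, "VolumePair"))
  format <- match.arg(format)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  n <- nSlices(volume)
  if (format == "png") {
    idx <- seq_len(n) - 1L
    imgF <- sprintf("image_%04d.png", idx)
    lvF <- sprintf("liver_mask_%04d.png", idx)
    tmF <- sprintf("tumor_mask_%04d.png", idx)
    for (i in seq_len(n)) {
      png::writePNG(volume@images[, , i], file.path(directory, imgF[i]))
      png::writePNG(volume@liverMasks[, , i], file.path(directory, lvF[i]))
      png::writePNG(volume@tumorMasks[, , i], file.path(directory, tmF[i]))
    }
    manifest <- data.frame(slice_index = idx, image_path = imgF,
                           liver_mask_path = lvF, tumor_mask_path = tmF,
                           stringsAsFactors = FALSE)
  } else {
    labels <- combineLabels(volume@liverMasks, volume@tumorMasks)
    img <- RNifti::asNifti(volume@images)
    lab <- RNifti::asNifti(array(as.integer(labels), dim(labels)))
    RNifti::pixdim(img) <- c(1, 1, volume@sliceSpacing)
    RNifti::pixdim(lab) <- c(1, 1, volume@sliceSpacing)
    RNifti::writeNifti(img, file.path(directory, "image.nii.gz"))
    RNifti::writeNifti(lab, file.path(directory, "labels.nii.gz"))
    manifest <- data.frame(slice_index = seq_len(n) - 1L,
                           image_path = "image.nii.gz",
                           liver_mask_path = "labels.nii.gz",
                           tumor_mask_path = "labels.nii.gz",
                           stringsAsFactors = FALSE)
  }
  utils::write.csv(manifest, file.path(directory, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by writeDataset back into a VolumePair
#'
#' @param directory dataset directory containing \code{manifest.csv}
#' @return a \linkS4class{VolumePair}
#' @export
readDataset <- function(directory) {
  mf <- file.path(directory, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv found in ", directory)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  paths <- file.path(directory, unique(c(manifest$image_path,
                                         manifest$liver_mask_path,
                                         manifest$tumor_mask_path)))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L)
    stop("manifest references missing file(s): ",
         paste(basename(missing), collapse = ", "))
  if (grepl("\\.nii(\\.gz)?$", manifest$image_path[1L])) {
    stripNifti <- function(x) array(as.vector(as.array(x)), dim(x))
    img <- stripNifti(RNifti::readNifti(
      file.path(directory, manifest$image_path[1L])))
    lab <- stripNifti(RNifti::readNifti(
      file.path(directory, manifest$liver_mask_path[1L])))
    sp <- splitCombinedLabels(lab)
    spc <- RNifti::pixdim(RNifti::readNifti(
      file.path(directory, manifest$image_path[1L])))
    return(VolumePair(img, sp$liver, sp$tumor,
                      sliceSpacing = if (length(spc) >= 3) spc[3] else 1))
  }
  n <- nrow(manifest)
  first <- png::readPNG(file.path(directory, manifest$image_path[1L]))
  d <- dim(first)[1:2]
  imgs <- array(0, c(d, n)); lv <- array(0, c(d, n)); tm <- array(0, c(d, n))
  for (i in seq_len(n)) {
    imgs[, , i] <- png::readPNG(file.path(directory, manifest$image_path[i]))
    lv[, , i] <- png::readPNG(file.path(directory,
                                        manifest$liver_mask_path[i]))
    tm[, , i] <- png::readPNG(file.path(directory,
                                        manifest$tumor_mask_path[i]))
  }
  VolumePair(imgs, (lv > 0.5) * 1, (tm > 0.5) * 1)
}
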
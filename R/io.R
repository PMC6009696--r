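# Scene and table I/O: multipage TIFF (channel-major pages, one page
# per z per channel) with a JSON sidecar carrying voxel size, channel
# metadata, seed and ground truth; expression tables as TSV.

#' Write a Scene to multipage TIFF plus JSON sidecar
#'
#' Pages are ordered channel-major (all z of channel 1, then channel 2,
#' ...). The sidecar `<base>.json` records voxel size, channel names
#' and roles, bit depth, seed and the geometric ground truth; the
#' truth's boolean nucleus mask (when present) is written as a separate
#' `<base>_truthmask.tif` referenced from the sidecar.
#'
#' @param scene a [`Scene`][Scene-class].
#' @param base output path without extension.
#' @return `base`, invisibly.
#' @export
writeScene <- function(scene, base) {
  stopifnot(methods::is(scene, "Scene"))
  dyn <- 2^scene@bitDepth - 1
  d <- dim(scene@voxels)
  pages <- list()
  for (ci in seq_len(d[4]))
    for (z in seq_len(d[3]))
      pages[[length(pages) + 1L]] <- scene@voxels[, , z, ci] / dyn
  tiff::writeTIFF(pages, paste0(base, ".tif"),
                  bits.per.sample = scene@bitDepth)
  truth <- scene@truth
  side <- list(
    format = "ctRadial-scene",
    dim = d,
    voxel_size = scene@voxelSize,
    channels = scene@channels,
    channel_roles = as.list(scene@channelRoles),
    bit_depth = scene@bitDepth,
    metadata = scene@metadata
  )
  if (length(truth)) {
    tr <- truth
    if (!is.null(tr$nucleusMask)) {
      mpages <- lapply(seq_len(dim(tr$nucleusMask)[3]), function(z)
        tr$nucleusMask[, , z] * 1.0)
      tiff::writeTIFF(mpages, paste0(base, "_truthmask.tif"),
                      bits.per.sample = 8)
      tr$nucleusMask <- NULL
      tr$truth_mask_file <- paste0(basename(base), "_truthmask.tif")
    }
    side$truth <- tr
  }
  jsonlite::write_json(side, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(base)
}

#' Read a Scene from TIFF (+ sidecar when present)
#'
#' With a `<base>.json` sidecar the round trip is lossless (voxels,
#' voxel size, metadata and truth). A bare multichannel TIFF can be
#' read by supplying `voxelSize` and `nChannels`; without either the
#' sidecar or `voxelSize`, reading fails with an error naming the
#' argument to supply.
#'
#' @param base path to the `.tif` file or its base name without
#'   extension.
#' @param voxelSize physical voxel size (um, length 3) when no sidecar
#'   is available.
#' @param nChannels number of channels for bare TIFFs (pages are
#'   assumed channel-major).
#' @param channels,channelRoles channel metadata for bare TIFFs.
#' @param bitDepth bit depth for bare TIFFs.
#' @return a [`Scene`][Scene-class].
#' @export
readScene <- function(base, voxelSize = NULL, nChannels = 3L,
                      channels = NULL, channelRoles = NULL,
                      bitDepth = 8L) {
  base <- sub("\\.tif$", "", base)
  tifPath <- paste0(base, ".tif")
  jsonPath <- paste0(base, ".json")
  if (!file.exists(tifPath)) stop("no such file: ", tifPath)
  pages <- tiff::readTIFF(tifPath, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (file.exists(jsonPath)) {
    side <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
    if (!identical(side$format, "ctRadial-scene"))
      stop("sidecar is not a ctRadial scene descriptor: ", jsonPath)
    d <- as.integer(side$dim)
    voxelSize <- as.numeric(side$voxel_size)
    channels <- as.character(side$channels)
    channelRoles <- unlist(side$channel_roles)
    bitDepth <- as.integer(side$bit_depth)
    truth <- side$truth
    metadata <- as.list(side$metadata)
  } else {
    if (is.null(voxelSize))
      stop("no sidecar found for ", tifPath, "; supply voxelSize = ",
           "c(x, y, z) in micrometres (and nChannels if not 3)")
    if (length(pages) %% nChannels != 0)
      stop("page count not divisible by nChannels")
    nz <- length(pages) %/% nChannels
    d <- c(dim(pages[[1]]), nz, nChannels)
    if (is.null(channels))
      channels <- c("blue", "green", "red")[seq_len(nChannels)]
    if (is.null(channelRoles)) {
      channelRoles <- stats::setNames(
        c("nucleus", rep("territory", nChannels - 1L)), channels)
    }
    truth <- NULL
    metadata <- list()
  }
  dyn <- 2^bitDepth - 1
  vox <- array(0, d)
  k <- 0L
  for (ci in seq_len(d[4]))
    for (z in seq_len(d[3])) {
      k <- k + 1L
      vox[, , z, ci] <- round(pages[[k]] * dyn)
    }
  truthList <- list()
  if (!is.null(truth)) {
    truthList <- truth
    if (!is.null(truth$truth_mask_file)) {
      mpath <- file.path(dirname(tifPath), truth$truth_mask_file)
      if (file.exists(mpath)) {
        mp <- tiff::readTIFF(mpath, all = TRUE)
        if (!is.list(mp)) mp <- list(mp)
        m <- array(FALSE, d[1:3])
        for (z in seq_along(mp)) m[, , z] <- mp[[z]] > 0.5
        truthList$nucleusMask <- m
      }
      truthList$truth_mask_file <- NULL
    }
    if (!is.null(truthList$territories) &&
        length(truthList$territories))
      truthList$territories <- as.data.frame(truthList$territories)
    if (!is.null(truthList$nucleusCenter))
      truthList$nucleusCenter <- as.numeric(truthList$nucleusCenter)
  }
  methods::new("Scene",
    voxels = vox, voxelSize = voxelSize, channels = channels,
    channelRoles = channelRoles, bitDepth = bitDepth,
    truth = truthList, metadata = metadata
  )
}

#' Write an expression table as TSV
#'
#' Header: `gene_id`, `chromosome`, `fpkm_<condition>` ...,
#' `log2fc_<condition>` ... (simulator provenance columns such as
#' `planted_<condition>` are kept when present).
#'
#' @param table expression data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpressionTable <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an expression table from TSV
#'
#' @param path TSV with the documented header.
#' @return data.frame.
#' @export
readExpressionTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("gene_id", "chromosome")
  if (!all(need %in% names(df)))
    stop("expression table must have columns gene_id and chromosome")
  if (!any(grepl("^fpkm_", names(df))))
    stop("expression table has no fpkm_<condition> columns")
  df
}
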
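## Volume I/O. The R stack here has no TIFF package, so a minimal
## uncompressed baseline-TIFF reader/writer is implemented directly:
## grayscale, multi-page (one page per z-slice), little-endian, 8/16-bit
## unsigned or 32-bit float, strip-organized. Enough to exchange volumes
## with tifffile/ImageJ; not a general TIFF library.

.TIFF_TYPESIZE <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

#' Write a 3-D volume as an uncompressed multi-page TIFF
#'
#' One grayscale page per z-slice, little-endian, single strip per page.
#' `type = "float"` writes 32-bit IEEE floats (intensity volumes);
#' `"uint8"`/`"uint16"` write unsigned integers (label volumes). Voxel sizes
#' are recorded as a JSON ImageDescription on the first page.
#'
#' @param vol 3-D numeric array `(nx, ny, nz)`.
#' @param path output file.
#' @param voxelSize `(dx, dy, dz)` in um, stored in the description.
#' @param type `"float"`, `"uint8"` or `"uint16"`.
#' @return `path`, invisibly.
#' @seealso [readVolumeTiff()]
#' @export
writeVolumeTiff <- function(vol, path, voxelSize = c(1, 1, 1),
                            type = c("float", "uint8", "uint16")) {
  type <- match.arg(type)
  d <- dim(vol)
  stopifnot(length(d) == 3L)
  nx <- d[1L]; ny <- d[2L]; nz <- d[3L]
  bytesPer <- switch(type, float = 4L, uint8 = 1L, uint16 = 2L)
  bits <- bytesPer * 8L
  sampleFormat <- if (type == "float") 3L else 1L
  desc <- charToRaw(jsonlite::toJSON(
    list(voxel_size_um = voxelSize, shape_xyz = d, writer = "microcapKP"),
    auto_unbox = FALSE))
  desc <- c(desc, as.raw(0L))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), as.raw(c(42L, 0L))), con)  # little-endian magic
  offset <- 8L                     # running file offset; IFD offsets patched in
  writeBin(0L, con, size = 4, endian = "little")         # placeholder: 1st IFD
  offset <- 8L

  stripBytes <- nx * ny * bytesPer
  entryCount <- function(z) if (z == 1L) 10L else 9L
  # plan offsets: pages written sequentially as [strip][desc?][IFD]
  ifdOffsets <- integer(nz)
  stripOffsets <- integer(nz)
  descOffset <- 0L
  cur <- 8L
  for (z in seq_len(nz)) {
    stripOffsets[z] <- cur
    cur <- cur + stripBytes
    if (z == 1L) {
      descOffset <- cur
      cur <- cur + length(desc)
      if (cur %% 2L == 1L) cur <- cur + 1L
    }
    ifdOffsets[z] <- cur
    cur <- cur + 2L + entryCount(z) * 12L + 4L
  }
  seek(con, 4L)
  writeBin(ifdOffsets[1L], con, size = 4, endian = "little")
  seek(con, 8L)

  writeEntry <- function(tag, typ, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(typ), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (typ == 3L && count == 1L) {            # SHORT inline
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (z in seq_len(nz)) {
    slice <- vol[, , z]
    # row-major pixel order: x fastest within each y-row
    v <- as.vector(slice)                       # column-major = x fastest
    if (type == "float") {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    } else {
      writeBin(as.integer(round(v)), con,
               size = bytesPer, endian = "little")
    }
    if (z == 1L) {
      writeBin(desc, con)
      if ((descOffset + length(desc)) %% 2L == 1L)
        writeBin(as.raw(0L), con)
    }
    writeBin(entryCount(z), con, size = 2, endian = "little")
    writeEntry(256L, 3L, 1L, nx)                # ImageWidth
    writeEntry(257L, 3L, 1L, ny)                # ImageLength
    writeEntry(258L, 3L, 1L, bits)              # BitsPerSample
    writeEntry(259L, 3L, 1L, 1L)                # Compression = none
    writeEntry(262L, 3L, 1L, 1L)                # Photometric = BlackIsZero
    if (z == 1L) writeEntry(270L, 2L, length(desc), descOffset)
    writeEntry(273L, 4L, 1L, stripOffsets[z])   # StripOffsets
    writeEntry(278L, 3L, 1L, ny)                # RowsPerStrip
    writeEntry(279L, 4L, 1L, stripBytes)        # StripByteCounts
    writeEntry(339L, 3L, 1L, sampleFormat)      # SampleFormat
    nxt <- if (z < nz) ifdOffsets[z + 1L] else 0L
    writeBin(nxt, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read an uncompressed multi-page TIFF into a 3-D volume
#'
#' Supports grayscale baseline TIFF (little- or big-endian), 8/16-bit
#' unsigned or 32-bit float samples, any strip layout, no compression.
#'
#' @param path TIFF file.
#' @return 3-D numeric array `(nx, ny, nz)` with attribute `voxel_size_um`
#'   when the file carries this package's JSON description.
#' @export
readVolumeTiff <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  endian <- if (rawToChar(raw[1:2]) == "II") "little" else "big"
  int <- function(at, size, signed = TRUE)
    readBin(raw[at:(at + size - 1L)], "integer", n = 1L, size = size,
            endian = endian, signed = signed)
  magic <- int(3L, 2L)
  if (magic != 42L) stop("not a TIFF file: ", path)
  ifdAt <- int(5L, 4L)
  slices <- list()
  voxel <- NULL
  while (ifdAt != 0L) {
    n <- int(ifdAt + 1L, 2L)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifdAt + 2L + (i - 1L) * 12L
      tag <- int(e + 1L, 2L, signed = FALSE)
      typ <- int(e + 3L, 2L)
      cnt <- int(e + 5L, 4L)
      sz <- .TIFF_TYPESIZE[typ]
      valAt <- if (cnt * sz <= 4L) e + 9L else int(e + 9L, 4L) + 1L
      val <- if (typ == 3L) {
        vapply(seq_len(cnt), function(k)
          int(valAt + (k - 1L) * 2L, 2L, signed = FALSE), integer(1))
      } else if (typ == 4L) {
        vapply(seq_len(cnt), function(k)
          int(valAt + (k - 1L) * 4L, 4L), integer(1))
      } else if (typ == 2L) {
        rawToChar(raw[valAt:(valAt + cnt - 2L)])
      } else NULL
      tags[[as.character(tag)]] <- val
    }
    g <- function(tag, default = NULL)
      if (!is.null(tags[[as.character(tag)]])) tags[[as.character(tag)]] else default
    if (g(259L, 1L)[1L] != 1L) stop("compressed TIFF not supported")
    if (g(277L, 1L)[1L] != 1L)
      stop("multi-sample (color/interleaved-channel) TIFF not supported")
    w <- g(256L); h <- g(257L)
    bits <- g(258L, 8L)[1L]
    fmt <- g(339L, 1L)[1L]
    offs <- g(273L); cnts <- g(279L)
    if (is.null(w) || is.null(h) || is.null(offs))
      stop("malformed TIFF IFD")
    if (!is.null(g(270L)) && is.null(voxel)) {
      meta <- tryCatch(jsonlite::fromJSON(g(270L)), error = function(e) NULL)
      if (!is.null(meta$voxel_size_um)) voxel <- meta$voxel_size_um
    }
    bytesPer <- bits / 8L
    vals <- numeric(0)
    for (s in seq_along(offs)) {
      at <- offs[s] + 1L
      nvals <- cnts[s] / bytesPer
      seg <- raw[at:(at + cnts[s] - 1L)]
      vals <- c(vals, if (fmt == 3L) {
        readBin(seg, "numeric", n = nvals, size = 4L, endian = endian)
      } else {
        readBin(seg, "integer", n = nvals, size = bytesPer, endian = endian,
                signed = bytesPer > 2L)
      })
    }
    if (bytesPer <= 2L && fmt == 1L) vals[vals < 0] <- vals[vals < 0] + 2^bits
    slices[[length(slices) + 1L]] <- matrix(vals, nrow = w)
    ifdAt <- int(ifdAt + 2L + n * 12L + 1L, 4L)
  }
  nx <- nrow(slices[[1L]]); ny <- ncol(slices[[1L]])
  vol <- array(unlist(slices), dim = c(nx, ny, length(slices)))
  if (!is.null(voxel)) attr(vol, "voxel_size_um") <- voxel
  vol
}

#' Write / read a ChannelStack as three TIFF volumes plus a JSON sidecar
#'
#' Channels are written in the acquisition order CW, AF594, FITC as
#' `<base>_cw.tif`, `<base>_af594.tif`, `<base>_fitc.tif`, with voxel sizes
#' and channel file names in `<base>.json`.
#'
#' @param stack a [ChannelStack-class].
#' @param base path prefix (no extension).
#' @return `writeChannelStack`: the sidecar path, invisibly;
#'   `readChannelStack`: a [ChannelStack-class].
#' @export
writeChannelStack <- function(stack, base) {
  files <- paste0(base, "_", c("cw", "af594", "fitc"), ".tif")
  writeVolumeTiff(channel(stack, "cw"), files[1L], voxelSize(stack))
  writeVolumeTiff(channel(stack, "af594"), files[2L], voxelSize(stack))
  writeVolumeTiff(channel(stack, "fitc"), files[3L], voxelSize(stack))
  side <- paste0(base, ".json")
  jsonlite::write_json(
    list(channels = list(cw = basename(files[1L]), af594 = basename(files[2L]),
                         fitc = basename(files[3L])),
         voxel_size_um = voxelSize(stack)),
    side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' @rdname writeChannelStack
#' @export
readChannelStack <- function(base) {
  side <- jsonlite::fromJSON(paste0(base, ".json"))
  dir <- dirname(base)
  rd <- function(f) {
    v <- readVolumeTiff(file.path(dir, f))
    attr(v, "voxel_size_um") <- NULL
    v
  }
  channelStack(rd(side$channels$cw), rd(side$channels$af594),
               rd(side$channels$fitc), as.numeric(side$voxel_size_um))
}

#' Write / read a DomainLabelVolume as an 8-bit TIFF
#'
#' Integer codes follow [DOMAIN_CODES]; a per-domain voxel-count CSV is
#' written alongside (`<path>.counts.csv`).
#'
#' @param labels a [DomainLabelVolume-class].
#' @param path output TIFF path.
#' @return `writeLabelVolume`: `path`, invisibly; `readLabelVolume`: a
#'   [DomainLabelVolume-class].
#' @export
writeLabelVolume <- function(labels, path) {
  writeVolumeTiff(labelArray(labels), path, voxelSize(labels), type = "uint8")
  cnt <- domainCounts(labels)
  utils::write.csv(data.frame(domain = names(cnt), voxels = as.integer(cnt)),
                   paste0(path, ".counts.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname writeLabelVolume
#' @export
readLabelVolume <- function(path) {
  vol <- readVolumeTiff(path)
  vs <- attr(vol, "voxel_size_um")
  domainLabelVolume(array(as.integer(vol), dim = dim(vol)),
                    if (is.null(vs)) 1 else vs)
}

#' Serialize / restore a phantom scenario as JSON
#'
#' Records the geometry, concentration field and imaging configuration of a
#' phantom so a scenario can be regenerated exactly.
#'
#' @param geometry a [MicrocapGeometry-class].
#' @param field a [ConcentrationField-class].
#' @param config an [ImagingConfig-class].
#' @param path JSON file.
#' @return `writeScenario`: `path`, invisibly; `readScenario`: a list with
#'   `geometry`, `field`, `config`.
#' @export
writeScenario <- function(geometry, field, config, path) {
  jsonlite::write_json(list(
    geometry = list(cap_center_xy = geometry@capCenter,
                    cap_radius = geometry@capRadius,
                    coupon_z = geometry@couponZ,
                    cw_penetration_depth = geometry@cwPenetrationDepth,
                    spheres = unname(apply(geometry@spheres, 1L, as.numeric,
                                           simplify = FALSE))),
    field = list(fitc_water = field@fitcWater,
                 fitc_hydrogel = field@fitcHydrogel,
                 fitc_microsphere = field@fitcMicrosphere,
                 cw_shell = field@cwShell, af594_sphere = field@af594Sphere,
                 coupon_reflection = field@couponReflection),
    config = list(dim = config@dim, voxel_size_xyz = config@voxelSize,
                  noise_model = config@noiseModel,
                  blur_sigma_xyz = config@blurSigma, seed = config@seed)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeScenario
#' @export
readScenario <- function(path) {
  s <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  sp <- s$geometry$spheres
  spm <- if (is.null(sp) || length(sp) == 0L) matrix(numeric(0), ncol = 4L)
         else if (is.matrix(sp)) sp else do.call(rbind, sp)
  geometry <- new("MicrocapGeometry",
                  capCenter = as.numeric(s$geometry$cap_center_xy),
                  capRadius = as.numeric(s$geometry$cap_radius),
                  couponZ = as.numeric(s$geometry$coupon_z),
                  spheres = spm,
                  cwPenetrationDepth = as.numeric(s$geometry$cw_penetration_depth))
  field <- concentrationField(s$field$fitc_water, s$field$fitc_hydrogel,
                              s$field$fitc_microsphere, s$field$cw_shell,
                              s$field$af594_sphere, s$field$coupon_reflection)
  config <- imagingConfig(s$config$dim, s$config$voxel_size_xyz,
                          as.list(s$config$noise_model),
                          s$config$blur_sigma_xyz, s$config$seed)
  list(geometry = geometry, field = field, config = config)
}
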
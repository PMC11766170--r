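# Data I/O: PGM image read/write, a minimal single-frame DICOM reader,
# preprocessing (resize + min-max normalisation), label mapping for
# CHAOS-style masks, and CSV manifests so synthetic and real data share one
# loading path.
#
# No PNG codec is available in this stack, so masks and grayscale images
# are stored as PGM (P5 binary / P2 ASCII, 8- or 16-bit); DICOM support is
# restricted to single-frame uncompressed little-endian files.

#' Write a grayscale image or mask as binary PGM
#'
#' @param img numeric matrix; values are scaled by `maxval` when `scale`
#'   (images in `[0,1]`), or written as-is (integer masks)
#' @param path output file
#' @param maxval 255 (8-bit) or 65535 (16-bit, big-endian per PGM spec)
#' @param scale multiply by maxval before rounding
#' @export
write_pgm <- function(img, path, maxval = 255L, scale = FALSE) {
  img <- as.matrix(img)
  v <- if (scale) round(img * maxval) else round(img)
  v <- pmin(pmax(v, 0), maxval)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  # PGM is row-major (English reading order)
  vt <- as.integer(t(v))
  if (maxval > 255L) {
    writeBin(as.raw(rbind(vt %/% 256L, vt %% 256L)), con)
  } else {
    writeBin(as.raw(vt), con)
  }
  invisible(path)
}

#' Read a PGM (P2 or P5) image
#' @param path file
#' @return list `(pixels = numeric matrix, maxval)`
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- character(0)
  # header: magic, width, height, maxval with comment support
  while (length(tok) < 4L) {
    ln <- readLines(con, n = 1L)
    ln <- sub("#.*", "", ln)
    tok <- c(tok, strsplit(trimws(ln), "\\s+")[[1]])
    tok <- tok[nzchar(tok)]
  }
  magic <- tok[1]
  w <- as.integer(tok[2]); h <- as.integer(tok[3]); mx <- as.integer(tok[4])
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  } else if (magic == "P5") {
    if (mx > 255L) {
      bytes <- readBin(con, "integer", n = 2L * w * h, size = 1L, signed = FALSE)
      vals <- bytes[c(TRUE, FALSE)] * 256L + bytes[c(FALSE, TRUE)]
    } else {
      vals <- readBin(con, "integer", n = w * h, size = 1L, signed = FALSE)
    }
  } else stop("not a PGM file: ", path)
  list(pixels = matrix(vals, h, w, byrow = TRUE), maxval = mx)
}

# ---- minimal DICOM ---------------------------------------------------------

dcm_u16 <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])
dcm_u32 <- function(raw4) sum(as.numeric(raw4) * c(1, 256, 65536, 16777216))

#' Read a single-frame uncompressed DICOM slice
#'
#' Supports explicit and implicit VR little endian transfer syntaxes,
#' 8/16-bit pixel data, and applies the rescale slope/intercept. Multi-frame
#' or compressed files are rejected.
#'
#' @param path DICOM file
#' @return list `(pixels = numeric matrix (rows x cols), rows, cols, slope,
#'   intercept)`
#' @export
load_dicom_slice <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  pos <- 133L
  tags <- list()
  explicit <- TRUE
  ts <- "1.2.840.10008.1.2.1"
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 8L <= length(raw) + 1L) {
    group <- dcm_u16(raw[pos:(pos + 1L)])
    elem <- dcm_u16(raw[(pos + 2L):(pos + 3L)])
    pos <- pos + 4L
    exp_here <- explicit || group == 2L  # file meta is always explicit
    if (exp_here) {
      vr <- rawToChar(raw[pos:(pos + 1L)])
      if (vr %in% long_vrs) {
        len <- dcm_u32(raw[(pos + 4L):(pos + 7L)])
        pos <- pos + 8L
      } else {
        len <- dcm_u16(raw[(pos + 2L):(pos + 3L)])
        pos <- pos + 4L
      }
    } else {
      len <- dcm_u32(raw[pos:(pos + 3L)])
      pos <- pos + 4L
    }
    if (len == 4294967295) stop("undefined-length element unsupported: ", path)
    val <- raw[pos:(pos + len - 1L)]
    pos <- pos + len
    key <- sprintf("%04x,%04x", group, elem)
    tags[[key]] <- val
    if (key == "0002,0010") {
      ts <- sub("\\s+$", "", rawToChar(val[val != as.raw(0L)]))
      if (ts == "1.2.840.10008.1.2") explicit <- FALSE
      else if (ts != "1.2.840.10008.1.2.1")
        stop("unsupported (compressed?) transfer syntax ", ts, " in ", path)
    }
    if (key == "7fe0,0010") break
  }
  num_tag <- function(key, default = NULL) {
    if (is.null(tags[[key]])) return(default)
    dcm_u16(tags[[key]][1:2])
  }
  str_tag <- function(key, default = NULL) {
    if (is.null(tags[[key]])) return(default)
    v <- tags[[key]]
    trimws(rawToChar(v[v != as.raw(0L)]))
  }
  nframes <- str_tag("0028,0008")
  if (!is.null(nframes) && as.integer(nframes) > 1L)
    stop("multi-frame DICOM unsupported: ", path)
  rows <- num_tag("0028,0010"); cols <- num_tag("0028,0011")
  bits <- num_tag("0028,0100", 16L)
  signed <- identical(num_tag("0028,0103", 0L), 1L)
  slope <- as.numeric(str_tag("0028,1053", "1"))
  inter <- as.numeric(str_tag("0028,1052", "0"))
  px <- tags[["7fe0,0010"]]
  if (is.null(rows) || is.null(cols) || is.null(px))
    stop("missing image data in DICOM file: ", path)
  if (bits == 16L) {
    vals <- readBin(px, "integer", n = rows * cols, size = 2L,
                    signed = signed, endian = "little")
    if (!signed) vals <- vals  # readBin size=2 signed=FALSE gives 0..65535
  } else {
    vals <- readBin(px, "integer", n = rows * cols, size = 1L, signed = signed)
  }
  pixels <- matrix(slope * as.numeric(vals) + inter, rows, cols, byrow = TRUE)
  list(pixels = pixels, rows = rows, cols = cols, slope = slope,
       intercept = inter)
}

# ---- preprocessing ---------------------------------------------------------

#' Resize to target x target (bilinear) and min-max normalise to [0, 1]
#'
#' Constant images map to all zeros (guarded division).
#'
#' @param image numeric matrix
#' @param target_size output side length
#' @return matrix `target_size x target_size` in `[0, 1]`
#' @export
preprocess <- function(image, target_size = 256L) {
  image <- as.matrix(image)
  d <- dim(image)
  if (any(d != target_size)) {
    x <- array(image, c(d[1], d[2], 1L, 1L))
    image <- resize_bilinear_cpp(x, target_size, target_size)[, , 1L, 1L]
  }
  rng <- range(image)
  if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1])
  else array(0, dim(image))
}

resize_nearest <- function(m, target) {
  d <- dim(m)
  ri <- pmin(pmax(round(((seq_len(target) - 0.5) * d[1]) / target + 0.5), 1L), d[1])
  ci <- pmin(pmax(round(((seq_len(target) - 0.5) * d[2]) / target + 0.5), 1L), d[2])
  m[ri, ci, drop = FALSE]
}

#' Map raw CHAOS-style mask intensities to class labels 0..4
#'
#' Ground-truth PNG/PGM encodings vary by release; positive intensities are
#' binned into the four foreground classes (liver, right kidney, left
#' kidney, spleen) in ascending order. Default bin edges are the quartiles
#' of the positive dynamic range; exact edges can be supplied. Resizing, if
#' requested, is nearest-neighbour so no new label values appear.
#'
#' @param raw_mask integer matrix of raw intensities (0 = background)
#' @param edges optional increasing vector of 3 inner bin edges
#' @param target_size optional output size
#' @return integer matrix with values in 0..4
#' @export
map_chaos_labels <- function(raw_mask, edges = NULL, target_size = NULL) {
  m <- as.matrix(raw_mask)
  pos <- m > 0
  out <- matrix(0L, nrow(m), ncol(m))
  if (any(pos)) {
    if (is.null(edges)) {
      mx <- max(m[pos])
      edges <- mx * c(0.25, 0.5, 0.75)
    }
    out[pos] <- 1L + findInterval(m[pos], edges, left.open = TRUE)
  }
  if (!is.null(target_size)) out <- resize_nearest(out, target_size)
  out
}

# ---- manifests and datasets ------------------------------------------------

#' Write a dataset of samples to disk (PGM images + masks + CSV manifest)
#'
#' @param samples list of `list(image, mask, source_id)` (e.g. from
#'   [generate_phantoms()])
#' @param dir output directory (created)
#' @param split split name recorded in the manifest
#' @return path of the manifest CSV
#' @export
write_dataset <- function(samples, dir, split = "train") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    id <- if (!is.null(s$source_id)) s$source_id else sprintf("sample_%03d", i)
    ip <- file.path(dir, paste0(id, "_img.pgm"))
    mp <- file.path(dir, paste0(id, "_mask.pgm"))
    write_pgm(s$image[, , 1L], ip, maxval = 65535L, scale = TRUE)
    write_pgm(s$mask, mp, maxval = 255L)
    data.frame(image = ip, mask = mp, split = split)
  })
  man <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mp, row.names = FALSE)
  mp
}

#' Load samples listed in a manifest CSV
#'
#' @param manifest_path CSV with columns image, mask, split
#' @param split optional split filter
#' @param target_size resize/normalise images (bilinear) and masks
#'   (nearest) to this side length; NULL keeps native size (images are
#'   still min-max normalised)
#' @return list of `list(image, mask, source_id)`
#' @export
load_manifest <- function(manifest_path, split = NULL, target_size = NULL) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!is.null(split)) man <- man[man$split == split, , drop = FALSE]
  if (!nrow(man)) stop("manifest is empty: ", manifest_path)
  base <- dirname(manifest_path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, basename(p))
  lapply(seq_len(nrow(man)), function(i) {
    ip <- resolve(man$image[i]); mp <- resolve(man$mask[i])
    img <- if (grepl("\\.dcm$", ip, ignore.case = TRUE))
      load_dicom_slice(ip)$pixels else read_pgm(ip)$pixels
    ts <- if (is.null(target_size)) nrow(img) else target_size
    img <- preprocess(img, ts)
    msk <- read_pgm(mp)$pixels
    if (!is.null(target_size)) msk <- resize_nearest(msk, target_size)
    list(image = array(img, c(dim(img), 1L)), mask = matrix(as.integer(msk), nrow(msk)),
         source_id = basename(ip))
  })
}
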
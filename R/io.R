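# File formats and run plumbing: FreeSurfer "curv" morphometry, ".annot"
# parcellations and binary surface geometry (all big-endian), channel
# standardization with persisted statistics, cohort directories that the
# synthetic and real-data paths share, and run manifests.

CURV_MAGIC <- as.raw(c(0xff, 0xff, 0xff))
SURF_MAGIC <- as.raw(c(0xff, 0xff, 0xfe))

#' Read a FreeSurfer curv (morphometry) file
#'
#' New-format dialect: 3-byte magic `0xFFFFFF`, int32 vertex count, int32 face
#' count, int32 values-per-vertex (must be 1), then big-endian float32 values.
#'
#' @param path File path.
#' @param expected_vertices Optional vertex count to validate against; a
#'   mismatch is an error, never a silent truncation.
#' @return Numeric vector of per-vertex values.
#' @export
read_fs_curv <- function(path, expected_vertices = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(magic, CURV_MAGIC))
    stop(sprintf("bad curv magic at byte 0 in '%s'", path))
  vnum <- readBin(con, "integer", 1, size = 4, endian = "big")
  readBin(con, "integer", 1, size = 4, endian = "big")  # face count (unused)
  vpv <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (vpv != 1L)
    stop(sprintf("unsupported values-per-vertex %d at byte 11 in '%s'", vpv, path))
  vals <- readBin(con, "numeric", vnum, size = 4, endian = "big")
  if (length(vals) != vnum)
    stop(sprintf("truncated curv file '%s': expected %d values, got %d",
                 path, vnum, length(vals)))
  if (!is.null(expected_vertices) && vnum != expected_vertices)
    stop(sprintf("curv file '%s' has %d vertices, expected %d",
                 path, vnum, expected_vertices))
  vals
}

#' @rdname read_fs_curv
#' @param values Numeric per-vertex vector to write.
#' @param fnum Face count to record in the header (metadata only).
#' @export
write_fs_curv <- function(values, path, fnum = 0L) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(CURV_MAGIC, con)
  writeBin(as.integer(c(length(values), fnum, 1L)), con, size = 4,
           endian = "big")
  writeBin(as.numeric(values), con, size = 4, endian = "big")
  invisible(path)
}

#' Read a FreeSurfer annot parcellation
#'
#' Binary dialect: int32 count, interleaved (vertex index, color code) int32
#' pairs, a colortable tag and a new-format (version -2) colortable whose
#' entries carry structure names and RGB codes (`code = r + 256 g + 65536 b`).
#' Codes are remapped to contiguous labels `0..n_rois-1` in colortable order;
#' vertices whose code is missing from the table get the reserved id `n_rois`
#' and are counted in a warning.
#'
#' @param path File path.
#' @return A `parcellation` object (labels, n_rois, names).
#' @export
read_fs_annot <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  n <- readBin(con, "integer", 1, size = 4, endian = "big")
  pairs <- readBin(con, "integer", 2 * n, size = 4, endian = "big")
  vtx <- pairs[seq(1, 2 * n, by = 2)]
  code <- pairs[seq(2, 2 * n, by = 2)]
  tag <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (length(tag) == 0 || tag != 1L)
    stop(sprintf("annot file '%s' has no colortable (tag != 1)", path))
  version <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (version >= 0)
    stop(sprintf("unsupported old-format colortable in '%s'", path))
  readBin(con, "integer", 1, size = 4, endian = "big")  # max structure id
  flen <- readBin(con, "integer", 1, size = 4, endian = "big")
  readBin(con, "raw", flen)                             # colortable filename
  n_entries <- readBin(con, "integer", 1, size = 4, endian = "big")
  names <- character(n_entries)
  codes <- integer(n_entries)
  for (i in seq_len(n_entries)) {
    readBin(con, "integer", 1, size = 4, endian = "big") # structure index
    slen <- readBin(con, "integer", 1, size = 4, endian = "big")
    nm <- readBin(con, "raw", slen)
    names[i] <- rawToChar(nm[nm != as.raw(0)])
    rgbt <- readBin(con, "integer", 4, size = 4, endian = "big")
    codes[i] <- rgbt[1] + 256L * rgbt[2] + 65536L * rgbt[3]
  }
  labels <- match(code, codes) - 1L
  n_missing <- sum(is.na(labels))
  if (n_missing > 0) {
    warning(sprintf("%d unlabeled vertices in '%s' assigned reserved id %d",
                    n_missing, path, n_entries))
    labels[is.na(labels)] <- n_entries
  }
  out <- integer(n)
  out[vtx + 1L] <- labels
  structure(list(labels = out, n_rois = n_entries, names = names),
            class = "parcellation")
}

#' @rdname read_fs_annot
#' @param parcellation A `parcellation` to write.
#' @export
write_fs_annot <- function(parcellation, path) {
  labels <- parcellation$labels
  nms <- parcellation$names
  if (is.null(nms)) nms <- sprintf("roi_%02d", seq_len(parcellation$n_rois) - 1L)
  n_entries <- parcellation$n_rois
  # distinct nonzero color codes: code i+1 for label i
  codes <- seq_len(n_entries)
  r <- codes %% 256L; g <- (codes %/% 256L) %% 256L; b <- codes %/% 65536L
  con <- file(path, "wb")
  on.exit(close(con))
  be_int <- function(x) writeBin(as.integer(x), con, size = 4, endian = "big")
  n <- length(labels)
  be_int(n)
  pairs <- integer(2 * n)
  pairs[seq(1, 2 * n, by = 2)] <- seq_len(n) - 1L
  pairs[seq(2, 2 * n, by = 2)] <- codes[labels + 1L]
  be_int(pairs)
  be_int(1L)            # colortable tag
  be_int(-2L)           # new-format version
  be_int(n_entries)     # max structure id
  fname <- charToRaw("synthetic.ctab")
  be_int(length(fname)); writeBin(fname, con)
  be_int(n_entries)
  for (i in seq_len(n_entries)) {
    be_int(i - 1L)
    nm <- charToRaw(nms[i])
    be_int(length(nm)); writeBin(nm, con)
    be_int(c(r[i], g[i], b[i], 0L))
  }
  invisible(path)
}

#' Read FreeSurfer binary surface geometry
#'
#' Triangle-file dialect: 3-byte magic `0xFFFFFE`, a comment line terminated
#' by two newlines, int32 vertex and face counts, float32 vertex coordinates
#' and int32 zero-based face indices, all big-endian.
#'
#' @param path File path.
#' @return List with `vertices` (V x 3) and `faces` (F x 3, 1-based).
#' @export
read_fs_surface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(magic, SURF_MAGIC))
    stop(sprintf("bad surface magic at byte 0 in '%s'", path))
  # comment: bytes until "\n\n"
  prev <- as.raw(0)
  repeat {
    b <- readBin(con, "raw", 1)
    if (length(b) == 0) stop(sprintf("truncated surface header in '%s'", path))
    if (prev == as.raw(10) && b == as.raw(10)) break
    prev <- b
  }
  vnum <- readBin(con, "integer", 1, size = 4, endian = "big")
  fnum <- readBin(con, "integer", 1, size = 4, endian = "big")
  verts <- readBin(con, "numeric", 3 * vnum, size = 4, endian = "big")
  faces <- readBin(con, "integer", 3 * fnum, size = 4, endian = "big")
  list(vertices = matrix(verts, vnum, 3, byrow = TRUE),
       faces = matrix(faces, fnum, 3, byrow = TRUE) + 1L)
}

#' @rdname read_fs_surface
#' @param vertices V x 3 coordinate matrix.
#' @param faces F x 3 index matrix (1-based).
#' @param comment Header comment string.
#' @export
write_fs_surface <- function(vertices, faces, path,
                             comment = "created by cortexdiff") {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(SURF_MAGIC, con)
  writeBin(charToRaw(paste0(comment, "\n\n")), con)
  writeBin(as.integer(c(nrow(vertices), nrow(faces))), con, size = 4,
           endian = "big")
  writeBin(as.numeric(t(vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(t(faces) - 1L), con, size = 4, endian = "big")
  invisible(path)
}

# ---- standardization --------------------------------------------------------

#' Standardize feature channels over a cohort
#'
#' Computes per-channel mean and sd over all vertices of all subjects (when
#' `stats` is absent) and applies `(x - mean) / sd`. Test subjects must be
#' transformed with the training cohort's persisted statistics, never their
#' own; pass those as `stats`.
#'
#' @param cohort A `cortex_cohort` (or plain list of `cortex_subject`).
#' @param stats Optional statistics from a previous call (data frame with
#'   `channel`, `mean`, `sd`).
#' @return The cohort with transformed features and the statistics attached
#'   as `attr(, "channel_stats")`.
#' @export
standardize_channels <- function(cohort, stats = NULL) {
  subjects <- if (inherits(cohort, "cortex_cohort")) cohort$subjects else cohort
  if (length(subjects) == 0) stop("empty cohort")
  ch <- colnames(subjects[[1]]$features)
  if (is.null(stats)) {
    all_feat <- do.call(rbind, lapply(subjects, `[[`, "features"))
    mu <- colMeans(all_feat)
    sd_ <- apply(all_feat, 2, stats::sd)
    if (any(sd_ == 0)) stop("constant channel cannot be standardized")
    stats <- data.frame(channel = ch, mean = mu, sd = sd_,
                        row.names = NULL, stringsAsFactors = FALSE)
  }
  subjects <- lapply(subjects, function(s) {
    s$features <- apply_channel_stats(s$features, stats)
    s
  })
  if (inherits(cohort, "cortex_cohort")) cohort$subjects <- subjects
  else cohort <- subjects
  attr(cohort, "channel_stats") <- stats
  cohort
}

#' @rdname standardize_channels
#' @param features V x C matrix with column names matching `stats$channel`.
#' @param inverse Apply the inverse transform `x * sd + mean`.
#' @export
apply_channel_stats <- function(features, stats, inverse = FALSE) {
  idx <- match(colnames(features), stats$channel)
  if (anyNA(idx)) stop("features have channels without stored statistics")
  mu <- stats$mean[idx]; sd_ <- stats$sd[idx]
  if (inverse) sweep(sweep(features, 2, sd_, `*`), 2, mu, `+`)
  else sweep(sweep(features, 2, mu, `-`), 2, sd_, `/`)
}

# ---- cohort directories -----------------------------------------------------

#' Write a cohort to a directory of FreeSurfer-format files
#'
#' One curv file per subject and channel (`<id>.<channel>.curv`), one per
#' subject for the mask, an annot file for the parcellation, a binary surface
#' for the sphere geometry and a `manifest.csv` of demographics, so synthetic
#' and real-data paths share one reader.
#'
#' @param cohort A `cortex_cohort`.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fnum <- nrow(cohort$ico$faces)
  for (s in cohort$subjects) {
    for (ch in colnames(s$features))
      write_fs_curv(s$features[, ch],
                    file.path(dir, sprintf("%s.%s.curv", s$subject_id, ch)),
                    fnum = fnum)
    write_fs_curv(s$mask, file.path(dir, sprintf("%s.mask.curv", s$subject_id)),
                  fnum = fnum)
  }
  write_fs_annot(cohort$parcellation, file.path(dir, "parcellation.annot"))
  write_fs_surface(cohort$ico$vertices, cohort$ico$faces,
                   file.path(dir, "sphere.surf"))
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  yaml::write_yaml(unclass(cohort$spec), file.path(dir, "spec.yaml"))
  invisible(dir)
}

#' @rdname write_cohort
#' @param channels Feature channels to read back.
#' @export
read_cohort <- function(dir, channels = c("ct", "si")) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  geo <- read_fs_surface(file.path(dir, "sphere.surf"))
  ord <- order_from_vertex_count(nrow(geo$vertices))
  ico <- ico_sphere(ord)
  parc <- read_fs_annot(file.path(dir, "parcellation.annot"))
  spec_file <- file.path(dir, "spec.yaml")
  spec <- if (file.exists(spec_file)) {
    sp <- yaml::read_yaml(spec_file)
    class(sp) <- "cohort_spec"
    sp
  } else NULL
  nv <- nrow(geo$vertices)
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$subject_id[i]
    feats <- vapply(channels, function(ch)
      read_fs_curv(file.path(dir, sprintf("%s.%s.curv", id, ch)), nv),
      numeric(nv))
    colnames(feats) <- channels
    mask <- as.integer(read_fs_curv(
      file.path(dir, sprintf("%s.mask.curv", id)), nv))
    structure(list(subject_id = id, features = feats, mask = mask,
                   age = manifest$age[i], sex = manifest$sex[i],
                   group = manifest$group[i]),
              class = "cortex_subject")
  })
  structure(list(subjects = subjects, manifest = manifest, ico = ico,
                 parcellation = parc, spec = spec),
            class = "cortex_cohort")
}

# ---- manifests --------------------------------------------------------------

#' Write a run manifest
#'
#' Records the seed, a hash of the configuration and arbitrary extra fields so
#' any run artifact can be regenerated from (config, seed).
#' @param dir Output directory.
#' @param config List describing the run configuration.
#' @param seed Integer seed of the run.
#' @param extra Named list of additional fields.
#' @export
write_manifest <- function(dir, config, seed, extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, cfg_file)
  hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  m <- c(list(seed = seed, config_md5 = hash,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), extra)
  jsonlite::write_json(m, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(m)
}
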
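#' Read a spatial sample from standard table dialects
#'
#' Supported count dialects: `"wide_table"` (features x wells, first column
#' feature id, header = well ids), `"long_table"` (columns feature, well,
#' value), `"triplet_matrix"` (MatrixMarket sparse matrix plus features and
#' barcodes files), and `"visium_dir"` (a directory holding `matrix.mtx`,
#' `features.tsv`, `barcodes.tsv` and `tissue_positions.csv`). All readers
#' are gzip-transparent. Positions come either as a plain table
#' (well_id, x, y; header optional) that is aligned to a lattice with
#' [align_to_lattice()], or as a Visium-style tissue positions CSV
#' (barcode, in_tissue, array_row, array_col, pixel_row, pixel_col) whose
#' rows with `in_tissue = 0` are dropped and whose array indices are used
#' directly as hexagonal lattice coordinates.
#'
#' Wells present in the positions file but absent from the matrix get zero
#' counts; matrix wells without a position are an error naming the well.
#'
#' @param counts path to the count table (or the `.mtx` for triplet input,
#'   or the directory for `visium_dir`).
#' @param positions path to the positions file (ignored for `visium_dir`).
#' @param format one of `"wide_table"`, `"long_table"`, `"triplet_matrix"`,
#'   `"visium_dir"`.
#' @param features,barcodes companion files for `"triplet_matrix"`.
#' @param lattice_type forwarded to [align_to_lattice()] (`NULL` = infer).
#' @return a `sample_data` (normalization `"raw"`).
#' @export
read_sample <- function(counts, positions = NULL,
                        format = c("wide_table", "long_table",
                                   "triplet_matrix", "visium_dir"),
                        features = NULL, barcodes = NULL,
                        lattice_type = NULL) {
  format <- match.arg(format)
  if (format == "visium_dir") {
    dirp <- counts
    counts <- .first_existing(file.path(dirp, c("matrix.mtx",
                                                "matrix.mtx.gz")))
    features <- .first_existing(file.path(dirp, c("features.tsv",
                                                  "features.tsv.gz")))
    barcodes <- .first_existing(file.path(dirp, c("barcodes.tsv",
                                                  "barcodes.tsv.gz")))
    positions <- .first_existing(file.path(dirp, c("tissue_positions.csv",
                                                   "tissue_positions.csv.gz",
                                                   "tissue_positions_list.csv")))
    format <- "triplet_matrix"
  }
  mat <- switch(format,
    wide_table = .read_wide(counts),
    long_table = .read_long(counts),
    triplet_matrix = .read_triplet(counts, features, barcodes))
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate feature ids: ",
         paste(utils::head(unique(rownames(mat)[duplicated(rownames(mat))]),
                           5L), collapse = ", "))
  }
  if (any(mat < 0)) stop("negative values in count matrix")
  pos <- read_positions(positions)
  missing_pos <- setdiff(colnames(mat), pos$well_id)
  if (length(missing_pos)) {
    stop("matrix wells without a position: ",
         paste(utils::head(missing_pos, 5L), collapse = ", "))
  }
  # matrix well order first, then position-only wells (zero counts)
  extra <- setdiff(pos$well_id, colnames(mat))
  if (length(extra)) {
    mat <- cbind(mat, matrix(0, nrow(mat), length(extra),
                             dimnames = list(NULL, extra)))
  }
  pos <- pos[match(colnames(mat), pos$well_id), , drop = FALSE]
  lat <- if (!is.null(pos$array_a)) {
    well_lattice(cbind(pos$array_a, pos$array_b), "hexagonal", 1,
                 well_ids = pos$well_id,
                 coords = if (!is.null(pos$x)) cbind(pos$x, pos$y))
  } else {
    align_to_lattice(cbind(pos$x, pos$y), lattice_type = lattice_type,
                     well_ids = pos$well_id)
  }
  sample_data(lat, mat, "raw")
}

.first_existing <- function(paths) {
  hit <- paths[file.exists(paths)][1L]
  if (is.na(hit)) stop("none of these files exist: ",
                       paste(paths, collapse = ", "))
  hit
}

.read_table_auto <- function(path, header) {
  sep <- if (grepl("\\.tsv(\\.gz)?$|\\.txt(\\.gz)?$", path)) "\t" else ","
  utils::read.table(path, header = header, sep = sep, quote = "\"",
                    comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

.read_wide <- function(path) {
  tab <- .read_table_auto(path, header = TRUE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in wide count table ", path)
  rownames(m) <- as.character(tab[[1L]])
  m
}

.read_long <- function(path) {
  tab <- .read_table_auto(path, header = TRUE)
  if (ncol(tab) < 3L) stop("long table needs (feature, well, value) columns")
  f <- as.character(tab[[1L]])
  w <- as.character(tab[[2L]])
  v <- tab[[3L]]
  if (!is.numeric(v)) stop("non-numeric value column in ", path)
  fu <- unique(f)
  wu <- unique(w)
  m <- matrix(0, length(fu), length(wu), dimnames = list(fu, wu))
  m[cbind(match(f, fu), match(w, wu))] <- v
  m
}

.read_triplet <- function(mtx, features, barcodes) {
  if (is.null(features) || is.null(barcodes)) {
    stop("triplet_matrix needs features and barcodes files")
  }
  con <- if (grepl("\\.gz$", mtx)) gzfile(mtx) else mtx
  m <- as.matrix(Matrix::readMM(con))
  feat <- .read_table_auto(features, header = FALSE)[[1L]]
  bc <- .read_table_auto(barcodes, header = FALSE)[[1L]]
  if (nrow(m) != length(feat) || ncol(m) != length(bc)) {
    stop(sprintf("matrix is %d x %d but features/barcodes have %d/%d entries",
                 nrow(m), ncol(m), length(feat), length(bc)))
  }
  dimnames(m) <- list(as.character(feat), as.character(bc))
  m
}

#' Read well positions (plain or Visium tissue-positions dialect)
#'
#' @param path positions file.
#' @return data frame with `well_id` and either `x`/`y` coordinates or
#'   `array_a`/`array_b` hexagonal lattice indices (Visium dialect; both
#'   when pixel coordinates are present).
#' @export
read_positions <- function(path) {
  if (is.null(path)) stop("a positions file is required")
  first <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path,
                     n = 1L)
  has_header <- grepl("[A-Za-z]", gsub("[eE][+-]?[0-9]+", "", first))
  tab <- .read_table_auto(path, header = has_header)
  nm <- tolower(names(tab))
  visium <- any(grepl("array_row", nm)) ||
    (!has_header && ncol(tab) == 6L && all(tab[[2L]] %in% c(0L, 1L)))
  if (visium) {
    if (!has_header) {
      names(tab) <- c("barcode", "in_tissue", "array_row", "array_col",
                      "pxl_row_in_fullres", "pxl_col_in_fullres")
    }
    nm <- tolower(names(tab))
    tab <- tab[tab[[which(nm == "in_tissue")]] == 1L, , drop = FALSE]
    row <- tab[[which(nm == "array_row")]]
    col <- tab[[which(nm == "array_col")]]
    if (any((col - row) %% 2L != 0L)) {
      stop("invalid Visium array indices: array_col/array_row parity mismatch")
    }
    px <- grep("pxl_col|pixel_col", nm)
    py <- grep("pxl_row|pixel_row", nm)
    out <- data.frame(well_id = as.character(tab[[1L]]),
                      array_a = (col - row) %/% 2L, array_b = row,
                      stringsAsFactors = FALSE)
    if (length(px) && length(py)) {
      out$x <- as.numeric(tab[[px[1L]]])
      out$y <- as.numeric(tab[[py[1L]]])
    }
    out
  } else {
    if (ncol(tab) < 3L) stop("positions table needs (well_id, x, y) columns")
    data.frame(well_id = as.character(tab[[1L]]),
               x = as.numeric(tab[[2L]]), y = as.numeric(tab[[3L]]),
               stringsAsFactors = FALSE)
  }
}

#' Counts-per-million normalization
#'
#' Scales every well's column to total 10^6. Wells with zero total counts
#' are left at zero with a warning. Note the intended degenerate case: for
#' a single-feature matrix cpm makes every occupied well equal, so the
#' feature's weights become uniform over occupied wells.
#'
#' @param sample a `sample_data` with normalization `"raw"`.
#' @return the sample with normalization `"cpm"`.
#' @export
cpm_normalize <- function(sample) {
  stopifnot(inherits(sample, "sample_data"))
  if (sample$normalization != "raw") stop("sample is already normalized")
  tot <- colSums(sample$matrix)
  zero <- tot == 0
  if (any(zero)) {
    warning(sum(zero), " well(s) with zero total counts left at zero")
    tot[zero] <- 1
  }
  sample$matrix <- sweep(sample$matrix, 2L, tot / 1e6, "/")
  sample$normalization <- "cpm"
  sample
}

#' Write / read a CoSS scores table
#'
#' Tab-separated, rows sorted by descending CoSS (ties by feature id);
#' scoring parameters and the package version go into `#`-prefixed header
#' lines so a written table documents its own provenance.
#'
#' @param table a `coss_table` (or compatible data frame).
#' @param path output file.
#' @export
write_scores <- function(table, path) {
  stopifnot(is.data.frame(table), "coss" %in% names(table))
  ord <- order(is.na(table$coss), -replace(table$coss, is.na(table$coss), 0),
               table$feature_id)
  tab <- table[ord, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cossr %s", as.character(utils::packageVersion("cossr"))),
             con)
  for (a in c("m", "p", "essential_policy", "l0")) {
    v <- attr(table, a)
    if (!is.null(v)) writeLines(sprintf("# %s=%s", a, format(v)), con)
  }
  suppressWarnings(utils::write.table(tab, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  hdr <- grep("^# ", readLines(path, n = 10L), value = TRUE)
  for (kv in hdr) {
    m <- regmatches(kv, regexec("^# ([a-z0-9_]+)=(.*)$", kv))[[1L]]
    if (length(m) == 3L) {
      v <- suppressWarnings(as.numeric(m[3L]))
      attr(tab, m[2L]) <- if (is.na(v)) m[3L] else v
    }
  }
  tab
}

#' Write a sample as a long table plus positions table
#'
#' Plain-text counterpart of [read_sample()] for the `simulate` verb:
#' `<prefix>_counts.tsv` (feature, well, value; zero entries omitted) and
#' `<prefix>_positions.tsv` (well_id, x, y). When a ground-truth attribute
#' is present it is written to `<prefix>_truth.tsv`.
#'
#' @param sample a `sample_data`.
#' @param prefix output path prefix.
#' @export
write_sample <- function(sample, prefix) {
  stopifnot(inherits(sample, "sample_data"))
  nz <- which(sample$matrix != 0, arr.ind = TRUE)
  long <- data.frame(feature = rownames(sample$matrix)[nz[, 1L]],
                     well = sample$lattice$well_ids[nz[, 2L]],
                     value = sample$matrix[nz],
                     stringsAsFactors = FALSE)
  long <- long[order(match(long$feature, rownames(sample$matrix)),
                     match(long$well, sample$lattice$well_ids)), ]
  utils::write.table(long, paste0(prefix, "_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pos <- data.frame(well_id = sample$lattice$well_ids,
                    x = sample$lattice$coords[, 1L],
                    y = sample$lattice$coords[, 2L])
  utils::write.table(pos, paste0(prefix, "_positions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gt <- attr(sample, "ground_truth")
  if (!is.null(gt)) {
    utils::write.table(gt, paste0(prefix, "_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(prefix)
}
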
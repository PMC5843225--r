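#' Construct a geographic point
#'
#' Latitude/longitude pair in decimal degrees, validated on construction.
#'
#' @param lat Latitude in degrees, in \[-90, 90\].
#' @param lon Longitude in degrees, in (-180, 180\].
#' @return An object of class `geo_point` with fields `lat` and `lon`.
#' @export
#' @examples
#' geo_point(0, 0)
geo_point <- function(lat, lon) {
  stopifnot(is.numeric(lat), is.numeric(lon), length(lat) == 1L, length(lon) == 1L)
  if (is.na(lat) || lat < -90 || lat > 90)
    stop("latitude must lie in [-90, 90], got ", lat)
  if (is.na(lon) || lon <= -180 || lon > 180)
    stop("longitude must lie in (-180, 180], got ", lon)
  structure(list(lat = lat, lon = lon), class = "geo_point")
}

#' @export
print.geo_point <- function(x, ...) {
  cat(sprintf("<geo_point %.4f, %.4f>\n", x$lat, x$lon))
  invisible(x)
}

#' Construct and validate a population table
#'
#' A population table holds one row per population: a unique name, the
#' cumulative migratory distance from the African origin in km, and the
#' allelic proportion of each marker. Optional `lat`/`lon` columns carry
#' population coordinates. Missing frequencies are explicit `NA`s; rows
#' with an `NA` are dropped per-model downstream (complete-case).
#'
#' @param df A data.frame with columns `population`, `distance_km`, then one
#'   numeric column per marker (values in \[0, 1\] or `NA`), and optionally
#'   `lat` and `lon`.
#' @return The validated data.frame, classed `population_table`, with a
#'   `markers` attribute listing the marker columns.
#' @export
population_table <- function(df) {
  stopifnot(is.data.frame(df))
  req <- c("population", "distance_km")
  if (!all(req %in% names(df)))
    stop("population table needs columns: ", paste(req, collapse = ", "))
  if (nrow(df) == 0L) stop("no records")
  if (anyDuplicated(df$population))
    stop("duplicated population names: ",
         paste(unique(df$population[duplicated(df$population)]), collapse = ", "))
  if (any(is.na(df$distance_km)) || any(df$distance_km < 0))
    stop("distance_km must be nonnegative and non-missing")
  markers <- setdiff(names(df), c(req, "lat", "lon"))
  for (m in markers) {
    p <- df[[m]]
    if (!is.numeric(p)) stop("marker column '", m, "' is not numeric")
    bad <- which(!is.na(p) & (p < 0 | p > 1))
    if (length(bad))
      stop("allele proportion outside [0,1] for marker '", m,
           "', row ", bad[1L], " (", df$population[bad[1L]], ")")
  }
  structure(df, class = c("population_table", "data.frame"), markers = markers)
}

#' Marker names of a population table
#' @param table A `population_table`.
#' @return Character vector of marker column names.
#' @export
markers <- function(table) attr(table, "markers")

#' Read a population table from TSV
#'
#' Expects a header `population  distance_km  <marker1> ...` (optional
#' `lat`, `lon`). Both `.` and `,` decimal separators are accepted so the
#' bundled table, which is transcribed with the decimal commas of the
#' printed source, round-trips bit-faithfully. The literal token `NA`
#' marks a missing frequency.
#'
#' @param path Path to a tab-separated file.
#' @return A `population_table`.
#' @export
read_population_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          na.strings = "NA")
  if (nrow(df) == 0L) stop("no records in ", path)
  num_cols <- setdiff(names(df), "population")
  for (cn in num_cols) df[[cn]] <- .parse_decimal(df[[cn]], cn, path)
  population_table(df)
}

.parse_decimal <- function(x, column, path) {
  out <- suppressWarnings(as.numeric(sub(",", ".", x, fixed = TRUE)))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop("malformed number '", x[bad[1L]], "' in column '", column,
         "', row ", bad[1L], " of ", path)
  out
}

#' Write a population table to TSV
#' @param table A `population_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct and validate a genetic-distance matrix
#'
#' Microsatellite-based squared genetic distances D-squared between
#' populations: symmetric, nonnegative, zero diagonal.
#'
#' @param D2 Numeric square matrix.
#' @param labels Population names (defaults to `rownames(D2)`).
#' @return A `drift_distance_matrix` (a classed matrix).
#' @export
drift_distance_matrix <- function(D2, labels = rownames(D2)) {
  D2 <- as.matrix(D2)
  n <- nrow(D2)
  if (n != ncol(D2)) stop("distance matrix must be square")
  if (is.null(labels)) labels <- paste0("pop", seq_len(n))
  if (length(labels) != n) stop("label length does not match matrix dimension")
  if (any(is.na(D2)) || any(D2 < 0)) stop("distances must be nonnegative, non-missing")
  if (max(abs(D2 - t(D2))) > 1e-9)
    stop("distance matrix asymmetric beyond 1e-9")
  if (any(diag(D2) != 0)) stop("distance matrix diagonal must be exactly 0")
  D2 <- (D2 + t(D2)) / 2  # symmetrize residual < 1e-9 noise
  dimnames(D2) <- list(labels, labels)
  structure(D2, class = c("drift_distance_matrix", class(matrix())))
}

#' Read a genetic-distance matrix from TSV
#'
#' Square numeric matrix with a leading label column and matching
#' row/column labels.
#'
#' @param path Path to a tab-separated file.
#' @return A `drift_distance_matrix`.
#' @export
read_drift_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  M <- as.matrix(df)
  if (!identical(rownames(M), colnames(M)))
    stop("row and column labels differ in ", path)
  storage.mode(M) <- "double"
  drift_distance_matrix(M, rownames(M))
}

#' Write a genetic-distance matrix to TSV
#' @param D A `drift_distance_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drift_matrix <- function(D, path) {
  df <- data.frame(population = rownames(D), as.data.frame(unclass(D)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled per-population migratory distances and SIRPB1-region allele frequencies
#'
#' The published table of 43 populations with their cumulative
#' Out-of-Africa migratory distance (km) and the allelic proportions of
#' nine SNPs flanking the SIRPB1 copy-number variant
#' (rs2263664, rs2253698, rs2746603, rs6074896, rs2209313, rs1535882,
#' rs11696842, rs6105421, rs4814391). Values are stored exactly as
#' printed (two decimals; the counted allele per marker is the one the
#' source printed, see the package vignette on orientation).
#'
#' @return A `population_table` with 43 rows and 9 markers.
#' @export
#' @examples
#' tab <- table1_fixture()
#' nrow(tab)
table1_fixture <- function() {
  path <- system.file("extdata", "table1_allele_frequencies.tsv",
                      package = "ooadrift", mustWork = TRUE)
  read_population_table(path)
}

## --- genotypes -------------------------------------------------------------

CNV_ALLELES <- c("Sin", "Dup")
SNP_ALLELES <- c("C", "T")

#' Construct and validate a two-locus genotype table
#'
#' Per-subject unordered genotypes at the CNV locus (alleles `Sin`
#' ancestral single copy, `Dup` duplicated) and the tagging SNP
#' (alleles `C`, `T`). Genotypes are written `"Sin/Dup"`, `"C/T"`, etc.;
#' allele order within a genotype is not meaningful and is normalized.
#'
#' @param df Data.frame with columns `subject`, `cnv`, `snp`.
#' @return The validated data.frame, classed `genotype_table`.
#' @export
genotype_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (!all(c("subject", "cnv", "snp") %in% names(df)))
    stop("genotype table needs columns subject, cnv, snp")
  if (nrow(df) == 0L) stop("genotype table is empty")
  df$cnv <- .normalize_genotype(df$cnv, CNV_ALLELES, "cnv")
  df$snp <- .normalize_genotype(df$snp, SNP_ALLELES, "snp")
  structure(df, class = c("genotype_table", "data.frame"))
}

.normalize_genotype <- function(g, alleles, locus) {
  parts <- strsplit(as.character(g), "/", fixed = TRUE)
  vapply(seq_along(parts), function(i) {
    a <- parts[[i]]
    if (length(a) != 2L || !all(a %in% alleles))
      stop("invalid ", locus, " genotype '", g[i], "' (alleles: ",
           paste(alleles, collapse = "/"), ")")
    paste(a[order(match(a, alleles))], collapse = "/")
  }, character(1))
}

#' Read a genotype table from TSV
#' @param path Tab-separated file with columns `subject`, `cnv`, `snp`.
#' @return A `genotype_table`.
#' @export
read_genotype_table <- function(path) {
  genotype_table(utils::read.delim(path, check.names = FALSE,
                                   colClasses = "character"))
}

## --- qPCR Ct records -------------------------------------------------------

#' Construct and validate qPCR Ct records for allele-specific 3C
#'
#' Long-format replicate threshold cycles: one row per (sample, amplicon
#' role, allele, replicate). Roles distinguish the genotyping `control`
#' amplicon from the conformation-sensing `sensor` amplicon.
#'
#' @param df Data.frame with columns `sample`, `role` (`control` or
#'   `sensor`), `allele` (`C` or `T`), `ct` (positive cycles).
#' @return The validated data.frame, classed `ct_records`.
#' @export
ct_records <- function(df) {
  stopifnot(is.data.frame(df))
  if (!all(c("sample", "role", "allele", "ct") %in% names(df)))
    stop("ct records need columns sample, role, allele, ct")
  if (!all(df$role %in% c("control", "sensor")))
    stop("role must be 'control' or 'sensor'")
  if (!all(df$allele %in% SNP_ALLELES)) stop("allele must be 'C' or 'T'")
  if (!is.numeric(df$ct) || any(is.na(df$ct)) || any(df$ct <= 0))
    stop("ct must be positive")
  structure(df, class = c("ct_records", "data.frame"))
}

#' Read Ct records from TSV
#' @param path Tab-separated file, see [ct_records()].
#' @return A `ct_records` data.frame.
#' @export
read_ct_records <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  ct_records(df)
}
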
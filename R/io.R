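#' Default column map for summary-statistics files
#'
#' Maps the package's canonical field names to the column names used in a
#' particular file. Override entries (or supply a YAML file via
#' [read_column_map()]) to read files with other headers.
#'
#' @return named list of column names.
#' @export
default_column_map <- function() {
  list(chrom = "chrom", pos = "pos", ref = "ref", alt = "alt",
       effect_allele = "effect_allele", beta = "beta", se = "se",
       z = "z", p = "p", eaf = "eaf", n = "n", info = "info", rsid = "rsid")
}

#' Read a column map from a YAML config file
#'
#' @param path YAML file with a top-level `columns:` mapping (or a flat
#'   mapping) of canonical field name to file column name.
#' @return named list usable as the `dialect` of [read_summary_stats()].
#' @export
read_column_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$columns)) cfg <- cfg$columns
  dialect <- default_column_map()
  for (nm in names(cfg)) dialect[[nm]] <- cfg[[nm]]
  dialect
}

#' Read per-variant association summary statistics
#'
#' Reads a tab-delimited file with a header and validates it into a
#' `summary_stats` data.frame. The score statistic z is derived as beta / se
#' when no z column is present, and p as the two-sided normal tail of z when
#' no p column is present. Row order is preserved.
#'
#' @param path file path.
#' @param dialect column-name mapping, see [default_column_map()].
#' @return data.frame of class `summary_stats` with canonical columns
#'   chrom, pos, ref, alt, rsid, id, effect_allele, beta, se, z, p, eaf, n,
#'   info (optional columns NA-filled when absent from the file).
#' @export
read_summary_stats <- function(path, dialect = default_column_map()) {
  if (!file.exists(path)) tl_stop(sprintf("file not found: %s", path), "transloci_io")
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  mandatory <- c("chrom", "pos", "ref", "alt", "beta", "se")
  for (field in mandatory) {
    if (!dialect[[field]] %in% names(raw)) {
      tl_stop(sprintf("missing mandatory column '%s' (mapped field '%s')",
                      dialect[[field]], field), "transloci_schema")
    }
  }
  get_col <- function(field) {
    nm <- dialect[[field]]
    if (!is.null(nm) && nm %in% names(raw)) raw[[nm]] else NULL
  }
  num_col <- function(field, required = FALSE) {
    x <- get_col(field)
    if (is.null(x)) return(NULL)
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !(is.na(x) | x %in% c("", "NA", ".")))
    if (length(bad)) {
      tl_stop(sprintf("unparseable numeric in column '%s' at line %d: '%s'",
                      dialect[[field]], bad[1] + 1L, x[bad[1]]),
              "transloci_parse")
    }
    v
  }
  variants <- variant_table(get_col("chrom"), num_col("pos"),
                            get_col("ref"), get_col("alt"),
                            rsid = get_col("rsid") %||% NA_character_)
  beta <- num_col("beta")
  se <- num_col("se")
  z <- num_col("z")
  p <- num_col("p")
  if (is.null(z)) z <- beta / se
  if (is.null(p)) p <- 2 * stats::pnorm(-abs(z))
  if (any(!is.na(p) & (p <= 0 | p > 1))) {
    bad <- which(!is.na(p) & (p <= 0 | p > 1))[1]
    tl_stop(sprintf("p-value outside (0, 1] at line %d: %g", bad + 1L, p[bad]),
            "transloci_validation")
  }
  eaf <- num_col("eaf")
  if (!is.null(eaf) && any(!is.na(eaf) & (eaf <= 0 | eaf >= 1))) {
    tl_stop("effect-allele frequencies must lie in (0, 1)", "transloci_validation")
  }
  effect <- get_col("effect_allele")
  if (is.null(effect)) effect <- variants$alt else effect <- toupper(effect)
  if (any(effect != variants$ref & effect != variants$alt)) {
    tl_stop("effect_allele must be one of ref/alt", "transloci_validation")
  }
  out <- cbind(variants,
               data.frame(effect_allele = effect, beta = beta, se = se, z = z,
                          p = p,
                          eaf = if (is.null(eaf)) NA_real_ else eaf,
                          n = num_col("n") %||% NA_real_,
                          info = num_col("info") %||% NA_real_,
                          stringsAsFactors = FALSE))
  class(out) <- c("summary_stats", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write summary statistics to a tab-delimited file
#'
#' The canonical column names are written, so a round trip through
#' [read_summary_stats()] with the default dialect is lossless.
#'
#' @param stats `summary_stats` data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  cols <- intersect(c("chrom", "pos", "ref", "alt", "rsid", "effect_allele",
                      "beta", "se", "z", "p", "eaf", "n", "info"), names(stats))
  df <- as.data.frame(stats)[, cols]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes into a dosage panel
#'
#' Supports VCF (GT or DS FORMAT fields; GT is converted to the count of alt
#' alleles) and a plain dosage matrix TSV (first column `sample_id`, one
#' column per variant named `chrom:pos:ref:alt`). Missing entries are imputed
#' to the variant's mean observed dosage (rate reported via message);
#' monomorphic variants are dropped with a warning.
#'
#' @param path input file.
#' @param format "vcf" or "dosage_matrix".
#' @param population population label attached to the panel.
#' @return a [genotype_panel()].
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage_matrix"),
                           population = "unknown") {
  format <- match.arg(format)
  if (!file.exists(path)) tl_stop(sprintf("file not found: %s", path), "transloci_io")
  if (format == "vcf") read_genotypes_vcf(path, population)
  else read_dosage_matrix(path, population)
}

read_genotypes_vcf <- function(path, population) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix)) # drop vcfR class
  variants <- variant_table(fix[, "CHROM"], as.integer(fix[, "POS"]),
                            fix[, "REF"], fix[, "ALT"],
                            rsid = ifelse(fix[, "ID"] == ".", NA, fix[, "ID"]))
  fmt <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":")))
  if ("DS" %in% fmt) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    dos <- t(ds)
  } else if ("GT" %in% fmt) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    clean <- gsub("\\|", "/", gt)
    n_all <- ifelse(is.na(clean), NA_integer_,
                    lengths(strsplit(clean, "/", fixed = TRUE)))
    if (length(unique(stats::na.omit(as.vector(n_all)))) > 1) {
      tl_stop("mixed ploidy in VCF GT field is unsupported", "transloci_format")
    }
    count_alt <- function(g) {
      if (is.na(g) || grepl("\\.", g)) return(NA_real_)
      sum(as.integer(strsplit(g, "/", fixed = TRUE)[[1]]) > 0)
    }
    dos <- t(apply(clean, c(1, 2), count_alt))
  } else {
    tl_stop("VCF has neither GT nor DS FORMAT fields", "transloci_format")
  }
  finalize_panel(dos, variants, rownames(dos), population)
}

read_dosage_matrix <- function(path, population) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id") {
    tl_stop("dosage matrix must have 'sample_id' as its first column",
            "transloci_schema")
  }
  ids <- names(df)[-1]
  parts <- strsplit(ids, ":", fixed = TRUE)
  if (any(lengths(parts) != 4L)) {
    tl_stop("dosage matrix column names must be chrom:pos:ref:alt",
            "transloci_schema")
  }
  km <- do.call(rbind, parts)
  variants <- variant_table(km[, 1], as.integer(km[, 2]), km[, 3], km[, 4])
  dos <- as.matrix(df[, -1, drop = FALSE])
  finalize_panel(dos, variants, df$sample_id, population)
}

# internal: shared missingness/monomorphic handling for genotype readers
finalize_panel <- function(dos, variants, sample_ids, population) {
  miss <- is.na(dos)
  if (any(miss)) {
    message(sprintf("imputing %d missing genotype(s) (%.2f%%) to variant mean dosage",
                    sum(miss), 100 * mean(miss)))
    mu <- colMeans(dos, na.rm = TRUE)
    idx <- which(miss, arr.ind = TRUE)
    dos[idx] <- mu[idx[, 2]]
  }
  genotype_panel(dos, variants, sample_ids, population, drop_monomorphic = TRUE)
}

#' Write a panel as a dosage-matrix TSV
#'
#' @param panel a `genotype_panel`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_dosage_matrix <- function(panel, path) {
  df <- data.frame(sample_id = panel$sample_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  dm <- as.data.frame(panel$dosages)
  dm[] <- lapply(dm, function(x) format(x, digits = 17, trim = TRUE))
  names(dm) <- panel$variants$id
  utils::write.table(cbind(df, dm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
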
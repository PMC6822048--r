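#' Read a Genepop file
#'
#' Parses the Genepop 4.x dialect: a title line, one locus name per line (or
#' a single comma-separated line), populations separated by lines reading
#' "POP" (any case), and individual lines of the form
#' `id , 012034 056056 ...` with 2- or 3-digit allele codes. The code
#' `00`/`000` is a missing allele; a call is treated as missing when either
#' allele is missing. The site id of a population is the id of its first
#' individual, truncated at the last separator-like suffix if all members
#' share it; otherwise `pop1`, `pop2`, ... are used.
#'
#' @param path path to a Genepop file.
#' @return a [genotype_dataset()].
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("not a Genepop file (too short): ", path)
  pop_re <- "^\\s*pop\\s*$"
  pop_at <- grep(pop_re, lines, ignore.case = TRUE)
  if (!length(pop_at)) stop("no POP separator found in ", path)
  header <- lines[2:(pop_at[1] - 1)]
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("no locus names in header of ", path)

  site <- character(0); id <- character(0)
  rows1 <- list(); rows2 <- list()
  pop_i <- 0L
  k <- 0L
  for (ln in seq(pop_at[1], length(lines))) {
    line <- lines[ln]
    if (grepl(pop_re, line, ignore.case = TRUE)) {
      pop_i <- pop_i + 1L
      next
    }
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2)
      stop("Genepop parse error at line ", ln, ": missing ',' separator")
    ind <- trimws(parts[1])
    geno <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    geno <- geno[nzchar(geno)]
    if (length(geno) != length(loci))
      stop("Genepop parse error at line ", ln, ": ", length(geno),
           " genotypes for ", length(loci), " loci")
    w <- nchar(geno[1]) / 2
    if (!w %in% c(2, 3) || any(nchar(geno) != 2 * w))
      stop("Genepop parse error at line ", ln, ": unknown allele-code width")
    x1 <- as.integer(substr(geno, 1, w))
    x2 <- as.integer(substr(geno, w + 1, 2 * w))
    miss <- x1 == 0L | x2 == 0L
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    k <- k + 1L
    site[k] <- paste0("pop", pop_i)
    id[k] <- ind
    rows1[[k]] <- x1; rows2[[k]] <- x2
  }
  if (anyDuplicated(id))
    stop("duplicate individual ids in ", path, ": ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  # recover site names from id prefixes when each population shares one
  ids_by_pop <- split(id, site)[unique(site)]
  prefixes <- vapply(ids_by_pop, function(v) {
    p <- sub("[._-][^._-]*$", "", v)
    if (length(unique(p)) == 1 && nzchar(p[1]) && !identical(p[1], v[1])) p[1] else NA_character_
  }, character(1))
  if (!anyNA(prefixes) && !anyDuplicated(prefixes)) {
    site <- prefixes[site]
    names(site) <- NULL
  }
  genotype_dataset(site, id, loci,
                   do.call(rbind, rows1), do.call(rbind, rows2))
}

#' Write a genotype dataset as a Genepop file
#'
#' @param data a [genotype_dataset()].
#' @param path output path.
#' @param title title line.
#' @param digits allele-code width, 2 or 3.
#' @export
write_genepop <- function(data, path, title = "poolscape export", digits = 3) {
  if (!digits %in% c(2, 3)) stop("digits must be 2 or 3")
  mx <- suppressWarnings(max(data$a1, data$a2, na.rm = TRUE))
  if (is.finite(mx) && mx >= 10^digits)
    stop("allele size ", mx, " does not fit in ", digits, " digits")
  fmt <- function(x) {
    out <- formatC(x, width = digits, flag = "0")
    out[is.na(x)] <- strrep("0", digits)
    out
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(data$loci, con)
  for (s in dataset_sites(data)) {
    writeLines("POP", con)
    rows <- which(data$site == s)
    for (r in rows) {
      g <- paste0(fmt(data$a1[r, ]), fmt(data$a2[r, ]))
      writeLines(paste0(data$id[r], " ,  ", paste(g, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Write genotypes as a long-form delimited table
#'
#' Columns: site, individual, locus, allele1, allele2 (NA for missing).
#' @param data a [genotype_dataset()].
#' @param path output path.
#' @export
write_genotypes_long <- function(data, path) {
  L <- length(data$loci); n <- length(data$id)
  df <- data.frame(
    site = rep(data$site, times = L),
    individual = rep(data$id, times = L),
    locus = rep(data$loci, each = n),
    allele1 = as.vector(data$a1),
    allele2 = as.vector(data$a2)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a long-form delimited table
#' @param path file written by [write_genotypes_long()] (or matching schema).
#' @return a [genotype_dataset()].
#' @export
read_genotypes_long <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("site", "individual", "locus", "allele1", "allele2")
  if (!all(need %in% names(df)))
    stop("long genotype table must have columns: ", paste(need, collapse = ", "))
  ids <- unique(df$individual)
  loci <- unique(df$locus)
  a1 <- matrix(NA_integer_, length(ids), length(loci), dimnames = list(ids, loci))
  a2 <- a1
  ii <- cbind(match(df$individual, ids), match(df$locus, loci))
  a1[ii] <- as.integer(df$allele1)
  a2[ii] <- as.integer(df$allele2)
  site <- df$site[match(ids, df$individual)]
  genotype_dataset(site, ids, loci, a1, a2)
}

#' Read a site coordinate table
#'
#' Expects columns `site`, `lat`, `lon` (WGS84 decimal degrees).
#' @param path delimited file.
#' @return data.frame with columns site, lat, lon.
#' @export
read_site_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("site", "lat", "lon") %in% names(df)))
    stop("site table must have columns site, lat, lon")
  validate_site_table(df[, c("site", "lat", "lon")])
}

validate_site_table <- function(df) {
  if (anyDuplicated(df$site)) stop("duplicate site ids in site table")
  if (any(abs(df$lat) > 90, na.rm = TRUE)) stop("latitude out of [-90, 90]")
  if (any(abs(df$lon) > 180, na.rm = TRUE)) stop("longitude out of [-180, 180]")
  df
}

#' Write a site coordinate table
#' @param sites data.frame with site, lat, lon.
#' @param path output path.
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(sites[, c("site", "lat", "lon")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load the study's site table with per-site diversity summaries
#'
#' Returns the published per-site table for the two focal amphibians
#' (90 spotted salamander and 87 wood frog vernal-pool populations in
#' Maine, USA): coordinates, sample sizes, counts of Hardy-Weinberg and
#' linkage-disequilibrium test rejections, mean alleles per locus (A_O),
#' rarefied allelic richness (AR), expected heterozygosity (H_E), and F_IS,
#' for each species. Rows where a species was not sampled hold NA.
#'
#' @param species "spotted_salamander", "wood_frog", or "all" (default); for
#'   a single species, rows without data for it are dropped and columns
#'   renamed to the plain names (n, hw, ld, ao, ar, he, fis).
#' @return data.frame.
#' @export
vernal_pool_sites <- function(species = c("all", "spotted_salamander", "wood_frog")) {
  species <- match.arg(species)
  path <- system.file("extdata", "vernal_pool_sites.tsv", package = "poolscape")
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (species == "all") return(df)
  pre <- if (species == "spotted_salamander") "ss_" else "wf_"
  cols <- paste0(pre, c("n", "hw", "ld", "ao", "ar", "he", "fis"))
  out <- df[!is.na(df[[paste0(pre, "n")]]), c("site", "lat", "lon", cols)]
  names(out) <- c("site", "lat", "lon", "n", "hw", "ld", "ao", "ar", "he", "fis")
  rownames(out) <- NULL
  out
}

#' Read an ESRI ASCII grid raster
#'
#' @param path `.asc` file with ncols/nrows/xllcorner/yllcorner/cellsize and
#'   optional NODATA_value header lines.
#' @return numeric matrix (rows = north to south) with attributes
#'   `xllcorner`, `yllcorner`, `cellsize`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[k]])) stop("ASCII grid header missing ", k, " in ", path)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid has ", length(vals), " cells, expected ",
         hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  attr(m, "xllcorner") <- hdr$xllcorner
  attr(m, "yllcorner") <- hdr$yllcorner
  attr(m, "cellsize") <- hdr$cellsize
  m
}

#' Write a matrix as an ESRI ASCII grid raster
#' @param m numeric matrix (rows north to south).
#' @param path output `.asc` path.
#' @param xllcorner,yllcorner,cellsize georeference (defaults from attributes
#'   or 0/0/1).
#' @param nodata value written for NA cells.
#' @export
write_ascii_grid <- function(m, path,
                             xllcorner = attr(m, "xllcorner") %||% 0,
                             yllcorner = attr(m, "yllcorner") %||% 0,
                             cellsize = attr(m, "cellsize") %||% 1,
                             nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(m)),
               paste("nrows", nrow(m)),
               paste("xllcorner", xllcorner),
               paste("yllcorner", yllcorner),
               paste("cellsize", cellsize),
               paste("NODATA_value", nodata)), con)
  m[is.na(m)] <- nodata
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
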
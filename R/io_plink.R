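#' Read PLINK text (PED/MAP) files into a genotype dataset
#'
#' The PED file is whitespace-delimited with the usual six leading columns
#' (family, individual, father, mother, sex, phenotype) followed by two allele
#' columns per marker; the family column is interpreted as the breed label and
#' the individual column as the sample id. Missing genotypes are the "0 0"
#' allele pair. The MAP file may have the package's six columns (chromosome,
#' marker id, genetic distance, position, allele_a, allele_b) or plain PLINK's
#' four, in which case alleles are inferred from the PED: the minor allele
#' becomes `allele_b` (ties and monomorphic markers resolved alphabetically,
#' a monomorphic marker's unseen allele written as "N").
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @return A [genotype_dataset()] with calls coded as `allele_b` dosage;
#'   markers sorted by (chromosome, position).
#' @seealso [write_plink_text()]
#' @export
read_plink_text <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stopf("PED file not found: %s", ped_path)
  if (!file.exists(map_path)) stopf("MAP file not found: %s", map_path)

  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(map_fields)
  if (length(nf) && !all(nf %in% c(4L, 6L))) {
    stopf("MAP parse error at line %d: expected 4 or 6 fields, found %d",
          which(!(nf %in% c(4L, 6L)))[1], nf[!(nf %in% c(4L, 6L))][1])
  }
  has_alleles <- length(nf) > 0 && all(nf == 6L)
  n_mark <- length(map_fields)
  map <- if (n_mark > 0) {
    as.data.frame(do.call(rbind, map_fields), stringsAsFactors = FALSE)
  } else {
    data.frame(V1 = character(), V2 = character(), V3 = character(),
               V4 = character())
  }

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n_samp <- length(ped_lines)
  breeds <- character(n_samp)
  ids <- character(n_samp)
  a1 <- matrix("0", n_samp, n_mark)
  a2 <- matrix("0", n_samp, n_mark)
  for (i in seq_len(n_samp)) {
    f <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(f) < 6) stopf("PED parse error at line %d: fewer than 6 columns", i)
    g <- f[-(1:6)]
    if (length(g) %% 2 != 0) {
      stopf("PED parse error at line %d: odd number of allele columns (%d)",
            i, length(g))
    }
    if (length(g) / 2 != n_mark) {
      stopf("PED parse error at line %d: %d genotype pairs but MAP lists %d markers",
            i, length(g) / 2, n_mark)
    }
    breeds[i] <- f[1]
    ids[i] <- f[2]
    if (n_mark > 0) {
      a1[i, ] <- g[c(TRUE, FALSE)]
      a2[i, ] <- g[c(FALSE, TRUE)]
    }
  }
  if (anyDuplicated(ids)) {
    stopf("duplicate sample_id in PED: %s", ids[duplicated(ids)][1])
  }

  if (has_alleles) {
    allele_a <- map[[5]]
    allele_b <- map[[6]]
  } else {
    allele_a <- character(n_mark)
    allele_b <- character(n_mark)
    for (j in seq_len(n_mark)) {
      obs <- c(a1[, j], a2[, j])
      obs <- sort(setdiff(unique(obs), "0"))
      if (length(obs) > 2) {
        stopf("marker %s has more than two alleles: %s",
              map[[2]][j], paste(obs, collapse = "/"))
      }
      if (length(obs) == 2) {
        cnt <- table(factor(c(a1[, j], a2[, j]), levels = obs))
        # minor allele is allele_b; alphabetic tie-break via the sort above
        allele_b[j] <- names(cnt)[which.min(cnt)]
        allele_a[j] <- setdiff(obs, allele_b[j])
      } else if (length(obs) == 1) {
        allele_a[j] <- obs
        allele_b[j] <- if (obs == "N") "A" else "N"
      } else {
        allele_a[j] <- "A"
        allele_b[j] <- "N"
      }
    }
  }

  calls <- matrix(NA_integer_, n_samp, n_mark)
  for (j in seq_len(n_mark)) {
    d <- (a1[, j] == allele_b[j]) + (a2[, j] == allele_b[j])
    known <- (a1[, j] %in% c(allele_a[j], allele_b[j])) &
      (a2[, j] %in% c(allele_a[j], allele_b[j]))
    miss <- a1[, j] == "0" | a2[, j] == "0"
    bad <- !known & !miss
    if (any(bad)) {
      stopf("PED parse error at line %d: allele '%s %s' not in {%s,%s} for marker %s",
            which(bad)[1], a1[bad, j][1], a2[bad, j][1],
            allele_a[j], allele_b[j], map[[2]][j])
    }
    d[miss] <- NA_integer_
    calls[, j] <- as.integer(d)
  }

  genotype_dataset(
    samples = data.frame(sample_id = ids, breed = breeds),
    markers = data.frame(
      marker_id = map[[2]], chromosome = map[[1]],
      position_bp = as.integer(map[[4]]),
      allele_a = allele_a, allele_b = allele_b
    ),
    calls = calls
  )
}

#' Write a genotype dataset as PLINK text (PED/MAP)
#'
#' Writes a six-column MAP (chromosome, marker id, genetic distance 0,
#' position, allele_a, allele_b) so that [read_plink_text()] round-trips the
#' dataset exactly. Missing calls are written as "0 0"; the breed label goes
#' into the PED family column.
#'
#' @param ds A [genotype_dataset()].
#' @param ped_path,map_path Output paths.
#' @return Invisibly, `ds`.
#' @export
write_plink_text <- function(ds, ped_path, map_path) {
  stopifnot(inherits(ds, "genotype_dataset"))
  m <- ds$markers
  writeLines(
    sprintf("%s\t%s\t0\t%d\t%s\t%s",
            m$chromosome, m$marker_id, m$position_bp, m$allele_a, m$allele_b),
    map_path
  )
  n_mark <- nrow(m)
  lines <- vapply(seq_len(nrow(ds$samples)), function(i) {
    g <- ds$calls[i, ]
    one <- ifelse(is.na(g), "0 0",
      ifelse(g == 0L, paste(m$allele_a, m$allele_a),
        ifelse(g == 1L, paste(m$allele_a, m$allele_b),
          paste(m$allele_b, m$allele_b))))
    paste(c(ds$samples$breed[i], ds$samples$sample_id[i], "0", "0", "0", "-9",
            one), collapse = "\t")
  }, character(1))
  writeLines(lines, ped_path)
  invisible(ds)
}

#' Merge two genotype datasets on their shared markers
#'
#' Markers are matched by id; alleles must agree, but a swapped
#' `allele_a`/`allele_b` labelling in the second dataset is harmonized by
#' flipping its dosages (g to 2 - g). Markers whose call rate over the merged
#' sample set is not strictly above `min_call_rate` are dropped.
#'
#' @param ds_a,ds_b [genotype_dataset()]s with disjoint sample ids.
#' @param min_call_rate Markers with post-merge call rate `<=` this value are
#'   removed (default 0.95).
#' @return A `genotype_dataset` with the union of samples and the filtered
#'   marker intersection.
#' @export
merge_intersect <- function(ds_a, ds_b, min_call_rate = 0.95) {
  stopifnot(inherits(ds_a, "genotype_dataset"), inherits(ds_b, "genotype_dataset"))
  clash <- intersect(ds_a$samples$sample_id, ds_b$samples$sample_id)
  if (length(clash)) {
    stopf("sample_id collision between datasets: %s", paste(clash, collapse = ", "))
  }
  shared <- intersect(ds_a$markers$marker_id, ds_b$markers$marker_id)
  if (!length(shared)) stopf("no shared markers between the two datasets")

  ia <- match(shared, ds_a$markers$marker_id)
  ib <- match(shared, ds_b$markers$marker_id)
  ma <- ds_a$markers[ia, ]
  mb <- ds_b$markers[ib, ]
  same <- ma$allele_a == mb$allele_a & ma$allele_b == mb$allele_b
  swapped <- ma$allele_a == mb$allele_b & ma$allele_b == mb$allele_a
  bad <- !(same | swapped)
  if (any(bad)) {
    stopf(
      "incompatible alleles at marker(s): %s",
      paste(sprintf("%s (%s/%s vs %s/%s)", shared[bad],
                    ma$allele_a[bad], ma$allele_b[bad],
                    mb$allele_a[bad], mb$allele_b[bad])[seq_len(min(5, sum(bad)))],
            collapse = ", ")
    )
  }
  calls_b <- ds_b$calls[, ib, drop = FALSE]
  if (any(swapped)) {
    calls_b[, swapped] <- 2L - calls_b[, swapped]
  }
  merged <- genotype_dataset(
    samples = rbind(ds_a$samples, ds_b$samples),
    markers = ma,
    calls = rbind(ds_a$calls[, ia, drop = FALSE], calls_b)
  )
  rate <- call_rate_report(merged)$per_marker
  keep <- merged$markers$marker_id[rate > min_call_rate]
  if (!length(keep)) {
    stopf("no shared marker passes the %.2f call-rate filter", min_call_rate)
  }
  subset(merged, markers = keep)
}
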
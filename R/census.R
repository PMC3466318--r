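#' Parse a tabular domain-hit file
#'
#' Reads a delimited table of protein-domain matches, one row per hit, as
#' produced by conserved-domain searches (CD-search, hmmscan and the like,
#' exported to TSV). Required columns: `protein_id`, `species_id`,
#' `domain_acc`, `domain_name`, `hit_class`, `start`, `end`, `evalue`.
#' `hit_class` must be one of `"specific"`, `"superfamily"`, `"multidomain"`;
#' coordinates are 1-based inclusive residue indices.
#'
#' @param path path to a tab-separated file with a header row, or a
#'   connection. Lines starting with `#` are ignored.
#' @return A data frame of class `domain_hits` with the columns above,
#'   `start`/`end` integer and `evalue` numeric.
#' @section Errors: a missing required column raises an error naming the
#'   column; a row with `start > end`, a negative `evalue`, or an unknown
#'   `hit_class` raises an error naming the offending line number(s).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(paste(
#'   c("protein_id\tspecies_id\tdomain_acc\tdomain_name\thit_class\tstart\tend\tevalue",
#'     "p1\ts1\tcd06170\tLuxR_C_like\tspecific\t150\t210\t1e-20"),
#'   collapse = "\n"), tf)
#' parse_domain_hits(tf)
parse_domain_hits <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("protein_id", "species_id", "domain_acc", "domain_name",
                "hit_class", "start", "end", "evalue")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols)) {
    stop("domain-hit table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d <- d[required]
  if (nrow(d) == 0) {
    d$start <- integer(0); d$end <- integer(0); d$evalue <- numeric(0)
    class(d) <- c("domain_hits", "data.frame")
    return(d)
  }
  d$start <- as.integer(d$start)
  d$end <- as.integer(d$end)
  d$evalue <- as.numeric(d$evalue)
  # data lines are offset by the header line
  line_no <- seq_len(nrow(d)) + 1L
  bad_class <- !d$hit_class %in% c("specific", "superfamily", "multidomain")
  if (any(bad_class)) {
    stop("unknown hit_class at line(s) ",
         paste(line_no[bad_class], collapse = ", "),
         " (expected specific/superfamily/multidomain)", call. = FALSE)
  }
  bad_coord <- is.na(d$start) | is.na(d$end) | d$start > d$end
  if (any(bad_coord)) {
    stop("invalid coordinates (start > end or non-integer) at line(s) ",
         paste(line_no[bad_coord], collapse = ", "), call. = FALSE)
  }
  bad_e <- is.na(d$evalue) | d$evalue < 0
  if (any(bad_e)) {
    stop("negative or missing evalue at line(s) ",
         paste(line_no[bad_e], collapse = ", "), call. = FALSE)
  }
  class(d) <- c("domain_hits", "data.frame")
  d
}

#' Retain proteins with a specific-class anchor-domain hit
#'
#' Applies the dual-filter retention rule of the census: a protein enters the
#' family only if it carries at least one hit to the anchor accession whose
#' hit class is `"specific"`. Superfamily- or multidomain-class matches to the
#' anchor do not qualify.
#'
#' @param hits a `domain_hits` data frame (see [parse_domain_hits()]).
#' @param anchor_acc anchor accession; default the LuxR_C_like domain
#'   [anchor_accession()].
#' @return Character vector of retained `protein_id`s (sorted, unique).
#' @export
filter_anchor_proteins <- function(hits, anchor_acc = anchor_accession()) {
  keep <- hits$domain_acc == anchor_acc & hits$hit_class == "specific"
  sort(unique(hits$protein_id[keep]))
}

#' Classify the domain architecture of one retained protein
#'
#' Keeps every specific-class hit of the protein (superfamily and multidomain
#' hits are discarded), maps accessions to short labels through the catalog,
#' and orders labels N- to C-terminal by ascending start coordinate (ties by
#' end, then accession). The architecture string joins the labels with `"+"`.
#' Repeated anchor hits are all kept. Overlapping specific hits are all kept.
#'
#' @param hits `domain_hits` rows for a single protein that passed
#'   [filter_anchor_proteins()].
#' @param catalog accession-to-label map, default [domain_catalog()].
#' @param unknown what to do with a specific hit whose accession is absent
#'   from the catalog: `"accession"` (default) keeps the accession as its
#'   label with a warning; `"error"` aborts.
#' @return A list of class `protein_architecture` with elements `protein_id`,
#'   `species_id`, `domains` (ordered label vector) and `architecture`
#'   (the joined string).
#' @export
#' @examples
#' h <- data.frame(protein_id = "p1", species_id = "s1",
#'                 domain_acc = c("cd00156", "cd06170"),
#'                 domain_name = c("REC", "LuxR_C_like"),
#'                 hit_class = "specific", start = c(5L, 150L),
#'                 end = c(120L, 210L), evalue = 0)
#' classify_architecture(h)$architecture  # "REC+LuxR"
classify_architecture <- function(hits, catalog = domain_catalog(),
                                  unknown = c("accession", "error")) {
  unknown <- match.arg(unknown)
  stopifnot(length(unique(hits$protein_id)) == 1L)
  sp <- hits[hits$hit_class == "specific", , drop = FALSE]
  if (nrow(sp) == 0) {
    stop("protein ", hits$protein_id[1],
         " has no specific-class hit; it should not have passed the anchor filter",
         call. = FALSE)
  }
  ord <- order(sp$start, sp$end, sp$domain_acc)
  sp <- sp[ord, , drop = FALSE]
  labels <- catalog_label(sp$domain_acc, catalog, unknown)
  structure(
    list(protein_id = hits$protein_id[1],
         species_id = hits$species_id[1],
         domains = labels,
         architecture = paste(labels, collapse = "+")),
    class = "protein_architecture"
  )
}

#' Classify every retained protein in a hit table
#'
#' Convenience wrapper: applies [filter_anchor_proteins()] then
#' [classify_architecture()] per protein.
#'
#' @inheritParams filter_anchor_proteins
#' @inheritParams classify_architecture
#' @return A list of `protein_architecture` objects.
#' @export
classify_all <- function(hits, anchor_acc = anchor_accession(),
                         catalog = domain_catalog(),
                         unknown = c("accession", "error")) {
  unknown <- match.arg(unknown)
  keep <- filter_anchor_proteins(hits, anchor_acc)
  lapply(keep, function(p) {
    classify_architecture(hits[hits$protein_id == p, , drop = FALSE],
                          catalog, unknown)
  })
}

#' Build a species-by-architecture census
#'
#' Counts proteins per (species, architecture string) pair. Ordering is
#' deterministic: species then architecture, lexicographic.
#'
#' @param architectures a list of `protein_architecture` objects, or a data
#'   frame with columns `species_id` and `architecture` (one row per
#'   protein).
#' @return An object of class `arch_census`: a data frame with columns
#'   `species_id`, `architecture`, `count`.
#' @export
build_census <- function(architectures) {
  if (is.data.frame(architectures)) {
    df <- architectures
    stopifnot(all(c("species_id", "architecture") %in% names(df)))
  } else {
    df <- data.frame(
      species_id = vapply(architectures, `[[`, "", "species_id"),
      architecture = vapply(architectures, `[[`, "", "architecture"),
      stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0) {
    out <- data.frame(species_id = character(0), architecture = character(0),
                      count = integer(0), stringsAsFactors = FALSE)
    class(out) <- c("arch_census", "data.frame")
    return(out)
  }
  agg <- aggregate(list(count = rep(1L, nrow(df))),
                   by = list(species_id = df$species_id,
                             architecture = df$architecture),
                   FUN = sum)
  agg <- agg[order(agg$species_id, agg$architecture), , drop = FALSE]
  rownames(agg) <- NULL
  agg$count <- as.integer(agg$count)
  class(agg) <- c("arch_census", "data.frame")
  agg
}

#' Read a census from a TSV file
#'
#' Expects columns `species_id`, `architecture`, `count`; lines starting with
#' `#` are ignored.
#' @param path file path.
#' @return An `arch_census` data frame.
#' @export
read_census <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("species_id", "architecture", "count")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("census table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d <- d[need]
  d$count <- as.integer(d$count)
  if (any(is.na(d$count) | d$count < 0)) stop("census counts must be non-negative integers")
  d <- d[order(d$species_id, d$architecture), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("arch_census", "data.frame")
  d
}

#' The packaged LuxR-family census fixture
#'
#' Loads the per-species, per-architecture counts of LuxR-domain regulators
#' across 53 actinobacterial genomes (11 architecture classes, 991 proteins
#' in total) that ship with the package.
#' @return An `arch_census` data frame.
#' @export
#' @examples
#' census_summary(table1_census())$grand_total  # 991
table1_census <- function() {
  read_census(system.file("extdata", "table1_census.tsv", package = "archevo",
                          mustWork = TRUE))
}

# round half away from zero to `digits`; printed census percentages use
# half-up rounding (59% from 588/991), unlike base round()'s banker rule
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarise an architecture census
#'
#' Family-level summaries: grand total, number of species, per-architecture
#' fractions, and the multidomain fraction (architectures with two or more
#' domains, i.e. anything beyond the bare anchor domain). Printed percentages
#' are rounded half-up to the nearest integer.
#'
#' @param census an `arch_census` data frame.
#' @param anchor_label label of the single-domain architecture (default
#'   `"LuxR"`); every other architecture counts as multidomain.
#' @return A list with `grand_total`, `n_species`, `fraction_multidomain`,
#'   `percent_multidomain`, `fraction_per_architecture` (named vector),
#'   `percent_per_architecture` (named integer vector) and
#'   `species_totals` (named integer vector of per-species family sizes).
#' @export
census_summary <- function(census, anchor_label = "LuxR") {
  if (nrow(census) == 0) stop("cannot summarise an empty census", call. = FALSE)
  grand <- sum(census$count)
  arch_tot <- tapply(census$count, census$architecture, sum)
  arch_tot <- arch_tot[order(names(arch_tot))]
  n_domains <- lengths(strsplit(names(arch_tot), "+", fixed = TRUE))
  multi <- sum(arch_tot[n_domains >= 2])
  sp_tot <- tapply(census$count, census$species_id, sum)
  frac <- as.numeric(arch_tot) / grand
  names(frac) <- names(arch_tot)
  list(
    grand_total = grand,
    n_species = length(sp_tot),
    fraction_multidomain = multi / grand,
    percent_multidomain = round_half_up(100 * multi / grand),
    fraction_per_architecture = frac,
    percent_per_architecture = setNames(round_half_up(100 * frac), names(frac)),
    species_totals = setNames(as.integer(sp_tot), names(sp_tot))
  )
}

#' Per-species sub-family summary table
#'
#' Collapses a census to the four response columns used by the correlation
#' battery: counts of the receiver-fused architecture, the single-domain
#' architecture, everything else, and the total family size per species.
#'
#' @param census an `arch_census`.
#' @param rec_label architecture string counted as `rec_luxr`
#'   (default `"REC+LuxR"`).
#' @param anchor_label architecture string counted as `luxr` (default
#'   `"LuxR"`).
#' @return Data frame with columns `species_id`, `rec_luxr`, `luxr`, `other`,
#'   `total`.
#' @export
census_subfamilies <- function(census, rec_label = "REC+LuxR",
                               anchor_label = "LuxR") {
  sp <- sort(unique(census$species_id))
  pick <- function(arch_filter) {
    vapply(sp, function(s) {
      sel <- census$species_id == s & arch_filter(census$architecture)
      as.integer(sum(census$count[sel]))
    }, integer(1))
  }
  data.frame(
    species_id = sp,
    rec_luxr = pick(function(a) a == rec_label),
    luxr = pick(function(a) a == anchor_label),
    other = pick(function(a) a != rec_label & a != anchor_label),
    total = pick(function(a) rep(TRUE, length(a))),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' @export
print.arch_census <- function(x, ...) {
  cat("Architecture census:", sum(x$count), "proteins,",
      length(unique(x$species_id)), "species,",
      length(unique(x$architecture)), "architectures\n")
  NextMethod()
}
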
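## Map asset schemas. All maps are delimited text with a header row.
.map_schemas <- list(
  icd_phecode = list(cols = c("icd", "flag", "phecode"),
                     key = c("icd", "flag", "phecode")),
  disease_phecode = list(cols = c("disease_id", "phecode"),
                         key = c("disease_id", "phecode")),
  disease_dx_icd = list(cols = c("disease_id", "icd", "flag"),
                        key = c("disease_id", "icd", "flag")),
  hpo_phecode = list(cols = c("hpo_term_id", "phecode", "match_quality"),
                     key = c("hpo_term_id", "phecode")),
  disease_hpo = list(cols = c("disease_id", "hpo_term_id", "gene",
                              "inheritance", "provisional"),
                     key = c("disease_id", "hpo_term_id"))
)

#' Load a map asset
#'
#' Reads one of the five map tables, validates its columns, and
#' deduplicates on the map's key. Map kinds and their columns:
#' \describe{
#'   \item{icd_phecode}{`icd`, `flag` (9/10), `phecode` — one ICD code may
#'     map to several phecodes.}
#'   \item{disease_phecode}{`disease_id`, `phecode` — the set of phecodes
#'     constituting each disease's clinical pattern. A user-supplied map is
#'     allowed to contain diseases with fewer than three phecodes; this is
#'     only warned about, since the three-phecode filter is a default of
#'     map construction, not of map use.}
#'   \item{disease_dx_icd}{`disease_id`, `icd`, `flag` — diagnostic ICD
#'     codes that denote a (genetic) diagnosis of the disease.}
#'   \item{hpo_phecode}{`hpo_term_id`, `phecode`, `match_quality`
#'     (exact/broader).}
#'   \item{disease_hpo}{`disease_id`, `hpo_term_id`, `gene`, `inheritance`,
#'     `provisional` (logical).}
#' }
#'
#' @param path Path to a delimited file.
#' @param kind Map kind, one of the names above.
#' @param delim Optional delimiter override.
#' @param verbose Log row counts.
#' @return A validated, keyed `data.table`.
#' @export
load_map <- function(path, kind, delim = NULL, verbose = TRUE) {
  kind <- match.arg(kind, names(.map_schemas))
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  sc <- .map_schemas[[kind]]
  dt <- data.table::fread(path, sep = .sniff_delim(path, delim),
                          colClasses = "character", na.strings = "NA",
                          showProgress = FALSE)
  .require_cols(dt, sc$cols, sprintf("%s map '%s'", kind, path))
  dt <- dt[, sc$cols, with = FALSE]

  if ("flag" %in% sc$cols) {
    dt[, flag := as.integer(flag)]
    if (!all(dt$flag %in% c(9L, 10L))) {
      stop(sprintf("%s map: flag must be 9 or 10", kind), call. = FALSE)
    }
  }
  if ("icd" %in% sc$cols) dt[, icd := trimws(icd)]
  if (kind == "hpo_phecode") {
    bad <- setdiff(unique(dt$match_quality), c("exact", "broader"))
    if (length(bad) > 0L) {
      stop(sprintf("hpo_phecode map: match_quality must be exact/broader, found: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  if (kind == "disease_hpo") {
    dt[, provisional := as.logical(
      ifelse(tolower(provisional) %in% c("true", "t", "1"), TRUE,
      ifelse(tolower(provisional) %in% c("false", "f", "0"), FALSE, NA)))]
    if (anyNA(dt$provisional)) {
      stop("disease_hpo map: provisional must be TRUE/FALSE", call. = FALSE)
    }
  }

  n0 <- nrow(dt)
  dt <- unique(dt, by = sc$key)
  if (nrow(dt) < n0) {
    .msg(verbose, "%s map: removed %d duplicate row(s)", kind, n0 - nrow(dt))
  }
  if (kind == "disease_phecode") {
    small <- dt[, .N, by = disease_id][N < 3L]
    if (nrow(small) > 0L) {
      warning(sprintf("disease_phecode map: %d disease(s) have fewer than 3 phecodes: %s",
                      nrow(small),
                      paste(head(small$disease_id, 5L), collapse = ", ")),
              call. = FALSE)
    }
  }
  data.table::setkeyv(dt, sc$key)
  .msg(verbose, "%s map: %d row(s) loaded from %s", kind, nrow(dt), path)
  dt[]
}

#' Build a disease-to-phecode map from annotation tables
#'
#' Joins disease-level HPO annotations to an HPO-term-to-phecode link table
#' to obtain, for each Mendelian disease, the set of phecodes describing
#' its clinical features. Annotation rows whose inheritance pattern is in
#' `exclude_inheritance` (matched case-insensitively; default
#' multifactorial, somatic, unspecified) or that are marked provisional are
#' dropped first. Exclusion is row-level: a disease annotated with both an
#' excluded and a retained inheritance (e.g. via different genes) keeps its
#' retained rows. After the join the result is deduplicated on
#' (disease, phecode) and diseases with fewer than `min_phecodes` distinct
#' phecodes are removed.
#'
#' @param annotations `disease_hpo` table (see [load_map()]).
#' @param links `hpo_phecode` table. `match_quality` is carried by the link
#'   table but not used here; filter the links beforehand to restrict to
#'   exact matches.
#' @param min_phecodes Minimum number of distinct phecodes a disease must
#'   have to be retained (default 3).
#' @param exclude_inheritance Character vector of inheritance patterns to
#'   drop.
#' @param verbose Log drop counts.
#' @return A `disease_phecode` map `data.table`. Empty (with a warning) if
#'   everything is filtered out.
#' @export
build_disease_phecode_map <- function(annotations, links, min_phecodes = 3L,
                                      exclude_inheritance = c("multifactorial",
                                                              "somatic",
                                                              "unspecified"),
                                      verbose = TRUE) {
  stopifnot(min_phecodes >= 1L)
  ann <- data.table::as.data.table(annotations)
  lnk <- data.table::as.data.table(links)
  .require_cols(ann, c("disease_id", "hpo_term_id", "inheritance",
                       "provisional"), "annotations")
  .require_cols(lnk, c("hpo_term_id", "phecode"), "links")

  excl <- tolower(trimws(exclude_inheritance))
  drop <- tolower(trimws(ann$inheritance)) %in% excl | ann$provisional
  .msg(verbose, "dropped %d of %d annotation row(s) (excluded inheritance or provisional)",
       sum(drop), nrow(ann))
  ann <- ann[!drop]

  merged <- merge(unique(ann[, .(disease_id, hpo_term_id)]),
                  unique(lnk[, .(hpo_term_id, phecode)]),
                  by = "hpo_term_id", allow.cartesian = TRUE)
  out <- unique(merged[, .(disease_id, phecode)])

  n_dis0 <- data.table::uniqueN(out$disease_id)
  out <- out[, if (.N >= min_phecodes) .SD, by = disease_id]
  if (!"phecode" %in% names(out)) {
    out <- data.table(disease_id = character(0), phecode = character(0))
  }
  .msg(verbose, "retained %d of %d disease(s) with >= %d distinct phecodes",
       data.table::uniqueN(out$disease_id), n_dis0, min_phecodes)
  if (nrow(out) == 0L) {
    warning("disease-phecode map is empty after filtering", call. = FALSE)
  }
  data.table::setkeyv(out, c("disease_id", "phecode"))
  out[]
}

#' Paths and loaders for the bundled toy map fixtures
#'
#' The package bundles small synthetic map fixtures (an ICD-to-phecode map
#' of ~40 codes, a 5-disease disease-phecode map, a 3-disease
#' diagnostic-ICD map, and toy HPO annotation/link tables) so that every
#' pipeline stage can run and be tested without downloading any ontology
#' release. These are illustrative fixtures, not curated clinical maps.
#'
#' @param kind Map kind as in [load_map()].
#' @param verbose Passed to [load_map()].
#' @return `example_map_path()` returns the file path; `example_map()`
#'   returns the loaded table.
#' @export
example_map_path <- function(kind) {
  kind <- match.arg(kind, names(.map_schemas))
  p <- system.file("extdata", paste0(kind, "_map.tsv"), package = "phescore")
  if (p == "") stop("bundled map fixture not found; is phescore installed?",
                    call. = FALSE)
  p
}

#' @rdname example_map_path
#' @export
example_map <- function(kind, verbose = FALSE) {
  load_map(example_map_path(kind), kind, verbose = verbose)
}
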
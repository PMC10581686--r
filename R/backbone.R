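#' Recognised taxonomic ranks and statuses
#'
#' Closed vocabularies for the backbone-cleaning step. Records whose
#' `taxonRank` or `taxonomicStatus` falls outside these sets are rejected
#' with an error naming the offending value, so that silently mislabelled
#' backbones are caught early.
#' @keywords internal
.backbone_ranks <- c("species", "subspecies", "variety", "form",
                     "genus", "family", "order", "class", "phylum", "kingdom",
                     "unranked")
.backbone_statuses <- c("accepted", "synonym", "doubtful")

#' Sampling configuration for the stratified taxonomic sample
#'
#' Bundles the quota rules used to draw a species sample stratified by order:
#' a base sampling fraction, bracket caps that bound the contribution of very
#' large orders, and an oversampling rule for tetrapods that mirrors the
#' long-standing vertebrate bias in biodiversity research ("institutional
#' vertebratism").
#'
#' @param base_fraction Fraction of species sampled from each order when no
#'   bracket cap applies. Default 0.002.
#' @param bracket_caps A data.frame with columns `lower`, `upper`, `quota`
#'   giving fixed quotas for orders whose species count falls in
#'   `[lower, upper]`. Defaults: 10001-50000 -> 20, 50001-100000 -> 40,
#'   >100000 -> 60. Brackets must be ordered and non-overlapping.
#' @param tetrapod_quota Species drawn from each tetrapod order (default 20).
#' @param small_tetrapod_threshold Tetrapod orders with fewer species than
#'   this draw `small_tetrapod_quota` instead (default 10).
#' @param small_tetrapod_quota Quota for small tetrapod orders (default 1).
#' @param tetrapod_classes Character vector of class names treated as
#'   tetrapods. Default `c("Amphibia", "Reptilia", "Aves", "Mammalia")`.
#' @param rounding How to round fractional `base_fraction * n` quotas:
#'   `"ceiling"` (default; every non-empty order contributes at least one
#'   species) or `"floor"`.
#' @param seed Integer seed used by [stratified_sample()].
#'
#' @return An object of class `sampling_config`.
#' @export
#' @examples
#' cfg <- sampling_config(seed = 1)
#' order_quota(30000, is_tetrapod = FALSE, cfg)  # 20
sampling_config <- function(base_fraction = 0.002,
                            bracket_caps = data.frame(
                              lower = c(10001, 50001, 100001),
                              upper = c(50000, 100000, Inf),
                              quota = c(20, 40, 60)),
                            tetrapod_quota = 20,
                            small_tetrapod_threshold = 10,
                            small_tetrapod_quota = 1,
                            tetrapod_classes = c("Amphibia", "Reptilia",
                                                 "Aves", "Mammalia"),
                            rounding = c("ceiling", "floor"),
                            seed = 1L) {
  rounding <- match.arg(rounding)
  stopifnot(is.numeric(base_fraction), base_fraction > 0, base_fraction <= 1)
  bc <- as.data.frame(bracket_caps)
  stopifnot(all(c("lower", "upper", "quota") %in% names(bc)))
  if (nrow(bc) > 1) {
    if (any(diff(bc$lower) <= 0) || any(bc$lower[-1] <= bc$upper[-nrow(bc)]))
      stop("bracket_caps must be ordered and non-overlapping")
  }
  if (any(bc$quota <= 0) || any(bc$quota != floor(bc$quota)))
    stop("bracket quotas must be positive integers")
  stopifnot(tetrapod_quota >= 1, small_tetrapod_quota >= 1,
            small_tetrapod_threshold >= 1)
  structure(list(base_fraction = base_fraction,
                 bracket_caps = bc,
                 tetrapod_quota = as.integer(tetrapod_quota),
                 small_tetrapod_threshold = as.integer(small_tetrapod_threshold),
                 small_tetrapod_quota = as.integer(small_tetrapod_quota),
                 tetrapod_classes = tetrapod_classes,
                 rounding = rounding,
                 seed = as.integer(seed)),
            class = "sampling_config")
}

#' Clean a GBIF-style backbone taxonomy
#'
#' Keeps exactly the rows usable for species-level sampling: accepted names
#' (`status == "accepted"`), at species rank (subspecies, varieties and other
#' ranks removed), and non-fossil records. Input order is preserved and the
#' operation is idempotent.
#'
#' @param records A data.frame of backbone rows with columns `taxon_id`,
#'   `name`, `rank`, `status`, `fossil` (logical), and the higher-taxonomy
#'   columns `kingdom`, `phylum`, `class_`, `order_`, `family`, `genus`.
#'   [read_backbone()] produces this layout from GBIF column names.
#' @return The retained rows, same columns, original order.
#' @export
clean_backbone <- function(records) {
  if (is.null(records) || nrow(records) == 0L) stop("no records")
  needed <- c("taxon_id", "name", "rank", "status", "fossil",
              "phylum", "class_", "order_")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("backbone is missing columns: ", paste(missing_cols, collapse = ", "))
  bad_status <- setdiff(unique(records$status), .backbone_statuses)
  if (length(bad_status))
    stop("unknown taxonomicStatus value: ", paste(bad_status, collapse = ", "))
  bad_rank <- setdiff(unique(records$rank), .backbone_ranks)
  if (length(bad_rank))
    stop("unknown taxonRank value: ", paste(bad_rank, collapse = ", "))
  keep <- records$status == "accepted" &
    records$rank == "species" &
    !as.logical(records$fossil)
  records[keep, , drop = FALSE]
}

#' Per-order sampling quota
#'
#' Number of species to draw from one order. Tetrapod orders draw a fixed
#' quota (`tetrapod_quota`, or `small_tetrapod_quota` below the small-order
#' threshold). Non-tetrapod orders draw a bracket cap when their size falls
#' in a configured bracket, otherwise `base_fraction * n` rounded per the
#' config. The result is always clamped to the order size.
#'
#' @param n_in_order Number of cleaned species in the order (>= 1).
#' @param is_tetrapod Logical; does the order belong to a tetrapod class?
#' @param cfg A [sampling_config()].
#' @return Integer quota, `1 <= quota <= n_in_order` (ceiling rounding) or
#'   `0 <= quota <= n_in_order` (floor rounding).
#' @export
order_quota <- function(n_in_order, is_tetrapod, cfg = sampling_config()) {
  stopifnot(length(n_in_order) == 1L, n_in_order >= 1)
  n <- as.numeric(n_in_order)
  if (isTRUE(is_tetrapod)) {
    q <- if (n < cfg$small_tetrapod_threshold) cfg$small_tetrapod_quota
         else cfg$tetrapod_quota
  } else {
    bc <- cfg$bracket_caps
    hit <- which(n >= bc$lower & n <= bc$upper)
    if (length(hit)) {
      q <- bc$quota[hit[1L]]
    } else {
      q <- switch(cfg$rounding,
                  ceiling = ceiling(cfg$base_fraction * n),
                  floor = floor(cfg$base_fraction * n))
    }
  }
  as.integer(min(q, n))
}

#' Stratified random species sample
#'
#' Draws, within every order present in the cleaned backbone, a uniform
#' random sample without replacement of size [order_quota()]. One global
#' generator is seeded from `cfg$seed` and orders are visited in sorted
#' name order, so the draw is reproducible across platforms.
#'
#' @param cleaned Output of [clean_backbone()].
#' @param cfg A [sampling_config()].
#' @return The sampled rows with an added `sampled_from_order` column. The
#'   per-order report (order, size, tetrapod flag, quota, drawn, seed) is
#'   attached as attribute `"report"`; see [sampling_report()].
#' @export
stratified_sample <- function(cleaned, cfg = sampling_config()) {
  if (is.null(cleaned) || nrow(cleaned) == 0L) stop("no records")
  ord <- as.character(cleaned$order_)
  blank <- is.na(ord) | ord == ""
  if (any(blank)) {
    warning(sum(blank), " record(s) without an order label skipped")
    cleaned <- cleaned[!blank, , drop = FALSE]
    ord <- ord[!blank]
  }
  if (nrow(cleaned) == 0L) stop("no records with order labels")
  orders <- sort(unique(ord))
  idx_by_order <- split(seq_len(nrow(cleaned)), ord)
  set.seed(cfg$seed)
  report <- vector("list", length(orders))
  take <- vector("list", length(orders))
  for (i in seq_along(orders)) {
    o <- orders[i]
    idx <- idx_by_order[[o]]
    n <- length(idx)
    cls <- unique(as.character(cleaned$class_[idx]))
    tet <- any(cls %in% cfg$tetrapod_classes)
    q <- order_quota(n, tet, cfg)
    drawn <- if (q > 0) sort(idx[sample.int(n, q)]) else integer(0)
    take[[i]] <- drawn
    report[[i]] <- data.frame(order_ = o, n_species = n, tetrapod = tet,
                              quota = q, drawn = length(drawn))
  }
  out <- cleaned[unlist(take), , drop = FALSE]
  out$sampled_from_order <- as.character(out$order_)
  rownames(out) <- NULL
  rep_df <- do.call(rbind, report)
  rep_df$seed <- cfg$seed
  attr(out, "report") <- rep_df
  out
}

#' Per-order sampling report
#'
#' @param sample Output of [stratified_sample()].
#' @return data.frame with one row per order: size, tetrapod flag, quota,
#'   species drawn, and the seed used.
#' @export
sampling_report <- function(sample) {
  rep <- attr(sample, "report")
  if (is.null(rep)) stop("no sampling report attached; not a stratified_sample result?")
  rep
}

#' Read a GBIF-style backbone table
#'
#' Reads a delimited backbone file using GBIF column names (`taxonID`,
#' `scientificName`, `taxonRank`, `taxonomicStatus`, `kingdom` ... `genus`,
#' plus a fossil-flag column) and renames to the package's internal layout.
#' The fossil flag may be logical, 0/1, or a `basisOfRecord` column in which
#' case rows equal to `"Fossil_Specimen"` are flagged.
#'
#' @param path File path.
#' @param sep Field separator; default tab.
#' @param fossil_col Name of the fossil-flag column (default `"fossil"`;
#'   `"basisOfRecord"` also understood).
#' @return data.frame in [clean_backbone()] layout.
#' @export
read_backbone <- function(path, sep = "\t", fossil_col = "fossil") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  map <- c(taxonID = "taxon_id", scientificName = "name",
           taxonRank = "rank", taxonomicStatus = "status",
           kingdom = "kingdom", phylum = "phylum", class = "class_",
           order = "order_", family = "family", genus = "genus")
  for (gbif in names(map)) {
    if (gbif %in% names(raw)) names(raw)[names(raw) == gbif] <- map[[gbif]]
  }
  if (!fossil_col %in% names(raw) && "basisOfRecord" %in% names(raw))
    fossil_col <- "basisOfRecord"
  if (!fossil_col %in% names(raw)) stop("no fossil-flag column found")
  fv <- raw[[fossil_col]]
  raw$fossil <- if (is.character(fv)) fv == "Fossil_Specimen" else as.logical(fv)
  raw
}

#' Write a sampled-species table and its JSON sampling report
#'
#' @param sample Output of [stratified_sample()].
#' @param tsv_path Output TSV path for the sampled species.
#' @param report_path Optional JSON path for the per-order report.
#' @return Invisibly, `tsv_path`.
#' @export
write_sample <- function(sample, tsv_path, report_path = NULL) {
  utils::write.table(sample, tsv_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(report_path)) {
    jsonlite::write_json(attr(sample, "report"), report_path,
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(tsv_path)
}
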
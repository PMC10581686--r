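# Species-level covariate engineering: IUCN regrouping and the model-ready
# transformed design shared by all count and residual models.

.iucn_codes <- c("EX", "EW", "CR", "EN", "VU", "NT", "LC", "DD", "NE")

#' Regroup the nine IUCN Red List codes into three levels
#'
#' Balances the factor levels used in the models: `Threatened` (EX, EW, CR,
#' EN, VU), `NonThreatened` (NT, LC) and `Unknown` (DD, NE).
#'
#' @param iucn_raw Character vector of IUCN codes.
#' @return Character vector in `{Threatened, NonThreatened, Unknown}`.
#' @export
#' @examples
#' regroup_iucn(c("EN", "LC", "NE"))
regroup_iucn <- function(iucn_raw) {
  iucn_raw <- as.character(iucn_raw)
  bad <- setdiff(unique(iucn_raw), .iucn_codes)
  if (length(bad)) stop("unknown IUCN code: ", paste(bad, collapse = ", "))
  out <- rep("Unknown", length(iucn_raw))
  out[iucn_raw %in% c("EX", "EW", "CR", "EN", "VU")] <- "Threatened"
  out[iucn_raw %in% c("NT", "LC")] <- "NonThreatened"
  out
}

.domain_levels <- c("multiple", "freshwater", "marine", "terrestrial")
.iucn_groups <- c("Unknown", "Threatened", "NonThreatened")

#' Fixed-effect covariates per model variant
#'
#' The full model uses organism size, colourfulness, range size, habitat
#' domain, family-level taxonomic uniqueness, common name, IUCN group, human
#' use, harmfulness, and phylogenetic distance to humans. The within-phylum
#' variant swaps family for genus uniqueness and drops phylogenetic distance
#' (too little resolution within a phylum).
#'
#' @param variant `"eq1"` (cross-phyla) or `"eq2"` (within-phylum).
#' @return Character vector of design column names, in model order.
#' @export
fixed_terms <- function(variant = c("eq1", "eq2")) {
  variant <- match.arg(variant)
  base <- c("log_size", "colorful", "log_range",
            "domain_freshwater", "domain_marine", "domain_terrestrial")
  uniq <- if (variant == "eq1") "log_family_uniq" else "log_genus_uniq"
  rest <- c("common_name", "iucn_Threatened", "iucn_NonThreatened",
            "human_use", "harmful")
  c(base, uniq, rest, if (variant == "eq1") "log_phylo_dist")
}

#' Default species-level vs cultural covariate grouping
#'
#' Grouping used by [variance_partition()]: species-level traits are
#' morphology/ecology (size, colour, range, domain, taxonomic uniqueness);
#' cultural factors reflect human perception and interaction (common name,
#' IUCN assessment, human use, harmfulness, phylogenetic distance to humans).
#'
#' @param variant `"eq1"` or `"eq2"`.
#' @return List with elements `species` and `culture`.
#' @export
covariate_groups <- function(variant = c("eq1", "eq2")) {
  variant <- match.arg(variant)
  ft <- fixed_terms(variant)
  culture <- intersect(c("common_name", "iucn_Threatened", "iucn_NonThreatened",
                         "human_use", "harmful", "log_phylo_dist"), ft)
  list(species = setdiff(ft, culture), culture = culture)
}

#' Build the model-ready design from species profiles
#'
#' Applies the transformations used throughout the analysis: natural-log on
#' organism size, range size, taxonomic uniqueness and phylogenetic distance
#' (`log(x)` for strictly positive size/distance/uniqueness, `log(1 + x)` for
#' range size, which is 0 for single-occurrence species); z-scoring of all
#' continuous covariates; and treatment-coded dummies with baselines
#' `domain = "multiple"` and `iucn_group = "Unknown"`. Blue/red colour flags
#' and model-organism status are carried in profiles but excluded from the
#' default designs (unbalanced in a random cross-taxon sample).
#'
#' @param profiles data.frame of species profiles; see [gen_profiles()] for
#'   the column contract (`size_mm`, `range_km`, `family_uniqueness`,
#'   `genus_uniqueness`, `phylo_dist_myr`, logical flags, `habitat_domain`,
#'   `iucn_group` or `iucn_raw`, plus grouping columns `phylum`, `class_`,
#'   `order_`, `region` and the responses `n_papers`, `n_views`).
#' @param variant `"eq1"` (default) or `"eq2"`.
#' @param transforms Optional transform parameters from a previous call, to
#'   reproduce a training design on new data (means/sds are reused, not
#'   re-estimated).
#' @return An object of class `interest_design`: list with `design` (numeric
#'   data.frame of fixed-effect columns, in [fixed_terms()] order), `groups`
#'   (data.frame of random-effect grouping keys: `phylum`, `class_in_phylum`,
#'   `order_in_class`, `region`), `y_papers`, `y_views`, `species_id`,
#'   `transforms`, and `variant`.
#' @export
prepare_design <- function(profiles, variant = c("eq1", "eq2"),
                           transforms = NULL) {
  variant <- match.arg(variant)
  pf <- as.data.frame(profiles)
  if (is.null(pf$iucn_group)) pf$iucn_group <- regroup_iucn(pf$iucn_raw)

  need <- c("size_mm", "range_km", "colorful", "common_name", "human_use",
            "harmful", "habitat_domain", "iucn_group",
            if (variant == "eq1") c("family_uniqueness", "phylo_dist_myr")
            else "genus_uniqueness")
  miss_col <- setdiff(need, names(pf))
  if (length(miss_col))
    stop("profiles missing columns: ", paste(miss_col, collapse = ", "))
  has_na <- need[vapply(pf[need], anyNA, logical(1))]
  if (length(has_na))
    stop("missing values in columns: ", paste(has_na, collapse = ", "))

  bad_dom <- setdiff(unique(as.character(pf$habitat_domain)), .domain_levels)
  if (length(bad_dom))
    stop("unknown habitat_domain level: ", paste(bad_dom, collapse = ", "))
  bad_iucn <- setdiff(unique(as.character(pf$iucn_group)), .iucn_groups)
  if (length(bad_iucn))
    stop("unknown iucn_group level: ", paste(bad_iucn, collapse = ", "))
  if (any(pf$size_mm <= 0)) stop("size_mm must be > 0")

  des <- data.frame(row.names = seq_len(nrow(pf)))
  des$log_size <- log(pf$size_mm)
  des$colorful <- as.numeric(pf$colorful)
  des$log_range <- log1p(pf$range_km)
  des$domain_freshwater <- as.numeric(pf$habitat_domain == "freshwater")
  des$domain_marine <- as.numeric(pf$habitat_domain == "marine")
  des$domain_terrestrial <- as.numeric(pf$habitat_domain == "terrestrial")
  if (variant == "eq1") {
    if (any(pf$family_uniqueness < 1)) stop("family_uniqueness must be >= 1")
    des$log_family_uniq <- log(pf$family_uniqueness)
  } else {
    if (any(pf$genus_uniqueness < 1)) stop("genus_uniqueness must be >= 1")
    des$log_genus_uniq <- log(pf$genus_uniqueness)
  }
  des$common_name <- as.numeric(pf$common_name)
  des$iucn_Threatened <- as.numeric(pf$iucn_group == "Threatened")
  des$iucn_NonThreatened <- as.numeric(pf$iucn_group == "NonThreatened")
  des$human_use <- as.numeric(pf$human_use)
  des$harmful <- as.numeric(pf$harmful)
  if (variant == "eq1") {
    if (any(pf$phylo_dist_myr <= 0)) stop("phylo_dist_myr must be > 0")
    des$log_phylo_dist <- log(pf$phylo_dist_myr)
  }
  des <- des[, fixed_terms(variant)]

  continuous <- grep("^log_", fixed_terms(variant), value = TRUE)
  if (is.null(transforms)) {
    transforms <- lapply(des[continuous], function(x) {
      m <- mean(x); s <- stats::sd(x)
      if (!is.finite(s) || s < 1e-12)
        stop("zero-variance continuous column in design")
      c(center = m, scale = s)
    })
  }
  for (cn in continuous) {
    tr <- transforms[[cn]]
    if (is.null(tr)) stop("no stored transform for column ", cn)
    des[[cn]] <- (des[[cn]] - tr["center"]) / tr["scale"]
  }

  groups <- NULL
  if (all(c("phylum", "class_", "order_") %in% names(pf))) {
    groups <- data.frame(
      phylum = as.character(pf$phylum),
      class_in_phylum = paste(pf$phylum, pf$class_, sep = "/"),
      order_in_class = paste(pf$phylum, pf$class_, pf$order_, sep = "/"),
      stringsAsFactors = FALSE)
    if ("region" %in% names(pf)) groups$region <- as.character(pf$region)
  }

  structure(list(design = des,
                 groups = groups,
                 y_papers = if ("n_papers" %in% names(pf)) pf$n_papers else NULL,
                 y_views = if ("n_views" %in% names(pf)) pf$n_views else NULL,
                 species_id = if ("species_id" %in% names(pf)) pf$species_id
                              else seq_len(nrow(pf)),
                 transforms = transforms,
                 variant = variant),
            class = "interest_design")
}

#' @export
print.interest_design <- function(x, ...) {
  cat("Model design (", x$variant, "): ", nrow(x$design), " species, ",
      ncol(x$design), " fixed-effect columns\n", sep = "")
  cat("  terms:", paste(names(x$design), collapse = ", "), "\n")
  if (!is.null(x$groups))
    cat("  grouping keys:", paste(names(x$groups), collapse = ", "), "\n")
  invisible(x)
}

#' Random-effect grouping terms per model variant
#'
#' The cross-phyla model uses nested taxonomic intercepts
#' (phylum / class-in-phylum / order-in-class, expanded to composite keys)
#' crossed with biogeographic region; the within-phylum variant drops the
#' phylum level.
#'
#' @param variant `"eq1"` or `"eq2"`.
#' @return Character vector of grouping-key column names.
#' @export
random_terms <- function(variant = c("eq1", "eq2")) {
  variant <- match.arg(variant)
  if (variant == "eq1")
    c("phylum", "class_in_phylum", "order_in_class", "region")
  else
    c("class_in_phylum", "order_in_class", "region")
}
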
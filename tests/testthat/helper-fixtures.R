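# Shared fixtures, built in code at test time.

# A small hand-written backbone exercising every cleaning rule.
make_backbone <- function() {
  data.frame(
    taxon_id = paste0("t", 1:8),
    name = paste("Genus sp", 1:8),
    rank = c("species", "species", "subspecies", "variety",
             "species", "species", "species", "genus"),
    status = c("accepted", "synonym", "accepted", "accepted",
               "accepted", "doubtful", "accepted", "accepted"),
    fossil = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    kingdom = "Animalia",
    phylum = "PhylumA",
    class_ = c(rep("ClassA", 4), rep("ClassB", 4)),
    order_ = c(rep("Order1", 4), rep("Order2", 4)),
    family = "FamA", genus = "GenA",
    stringsAsFactors = FALSE)
}

# A synthetic backbone with one order of a given size (non-tetrapod unless
# class is in the default tetrapod set).
make_order <- function(n, order = "OrderX", class_ = "ClassX",
                       phylum = "PhylumX", id_offset = 0L) {
  data.frame(
    taxon_id = paste0("s", id_offset + seq_len(n)),
    name = paste("Sp", id_offset + seq_len(n)),
    rank = "species", status = "accepted", fossil = FALSE,
    kingdom = "Animalia", phylum = phylum, class_ = class_, order_ = order,
    family = paste0(order, "_F"), genus = paste0(order, "_G"),
    stringsAsFactors = FALSE)
}

# Profiles with every column the design contract needs, deterministic.
make_profiles <- function(n = 60, seed = 11) {
  tx <- gen_taxonomy(n, n_phyla = 2, n_classes = 4, n_orders = 8, seed = seed)
  gen_profiles(tx, generator_config(seed = seed, n_phyla = 2))
}

# Fixed-effects-only simulated counts for fitter tests.
sim_counts <- function(n, family = c("poisson", "nb2", "zinb2"),
                       beta = c(1, 0.5, 0.7), theta = 0.7, pi = 0.3,
                       seed = 1) {
  family <- match.arg(family)
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.3)
  mu <- exp(beta[1] + beta[2] * x1 + beta[3] * x2)
  y <- switch(family,
              poisson = rpois(n, mu),
              nb2 = rnbinom(n, size = theta, mu = mu),
              zinb2 = ifelse(runif(n) < pi, 0L,
                             rnbinom(n, size = theta, mu = mu)))
  list(design = data.frame(x1 = x1, x2 = x2), y = y, mu = mu,
       beta = beta, theta = theta, pi = pi)
}

fixed_only_spec <- function(family, terms = c("x1", "x2")) {
  count_model_spec("papers", family, fixed_terms = terms,
                   random_terms = character(0))
}
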
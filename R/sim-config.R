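#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' study conditions the package is designed around: extended pedigrees,
#' blood-pressure-like traits with polygenic + person-level + occasion-level
#' variance (0.5 / 0.5 / 2.0), common SNPs (MAF >= 5%), and up to 4 visits
#' spaced 5 years apart.
#'
#' @param n_pedigrees Number of pedigree replicates of the template.
#' @param pedigree_template `"sibship"`, `"nuclear"` (2 founder parents plus
#'   `template_size` full siblings) or `"three_generation"` (12 members:
#'   grandparent couple, two of their children with married-in spouses, and
#'   three grandchildren per couple).
#' @param template_size Number of siblings for the sibship/nuclear templates.
#' @param mafs Minor allele frequencies of the simulated SNPs; must lie in
#'   \[0.05, 0.5\] (common variants). Recycled/overridden by `n_snps` draws
#'   from U(0.05, 0.5) when `NULL`.
#' @param n_snps Number of SNPs to gene-drop when `mafs` is `NULL`.
#' @param beta_snp Causal SNP effect in trait units per dosage unit.
#' @param beta_covars Named vector of fixed effects: `intercept`, `age`
#'   (per year), `sex` (male vs female), `smoke`.
#' @param var_polygenic,var_person,var_occasion Variance components: the
#'   kinship-structured polygenic variance, the i.i.d. person-level variance,
#'   and the per-visit occasion variance (all in squared trait units).
#' @param n_visits Visits per person (1-4).
#' @param visit_gap_years Years between consecutive visits.
#' @param dropout Probability that an individual attends only the baseline
#'   exam (missing-completely-at-random follow-up loss).
#' @param medication `NULL` for no medication masking, or
#'   `list(threshold = t, effect = d)`: visits whose latent trait exceeds
#'   `t` are flagged medicated and observed at `latent - d`.
#' @param seed Integer seed making every generated artifact reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pedigrees = 20,
                       pedigree_template = c("three_generation", "sibship", "nuclear"),
                       template_size = 4,
                       mafs = NULL,
                       n_snps = 100,
                       beta_snp = 0,
                       beta_covars = c(intercept = 120, age = 0.4, sex = 3, smoke = 2),
                       var_polygenic = 0.5,
                       var_person = 0.5,
                       var_occasion = 2,
                       n_visits = 4,
                       visit_gap_years = 5,
                       dropout = 0,
                       medication = NULL,
                       seed = 1L) {
  pedigree_template <- match.arg(pedigree_template)
  stopifnot(
    n_pedigrees >= 1, template_size >= 1,
    var_polygenic >= 0, var_person >= 0, var_occasion >= 0,
    n_visits >= 1, n_visits <= 4, visit_gap_years > 0,
    dropout >= 0, dropout < 1
  )
  if (!is.null(mafs) && (any(mafs < 0.05) || any(mafs > 0.5))) {
    stop("mafs must lie in [0.05, 0.5] (common variants only)")
  }
  req <- c("intercept", "age", "sex", "smoke")
  if (!all(req %in% names(beta_covars))) {
    stop("beta_covars must name: ", paste(req, collapse = ", "))
  }
  if (!is.null(medication) &&
      !all(c("threshold", "effect") %in% names(medication))) {
    stop("medication must be NULL or list(threshold =, effect =)")
  }
  structure(list(
    n_pedigrees = as.integer(n_pedigrees),
    pedigree_template = pedigree_template,
    template_size = as.integer(template_size),
    mafs = mafs, n_snps = as.integer(n_snps),
    beta_snp = beta_snp, beta_covars = beta_covars,
    var_polygenic = var_polygenic, var_person = var_person,
    var_occasion = var_occasion,
    n_visits = as.integer(n_visits), visit_gap_years = visit_gap_years,
    dropout = dropout, medication = medication,
    seed = as.integer(seed)
  ), class = "sim_config")
}
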
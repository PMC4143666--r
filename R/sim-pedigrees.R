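#' Generate pedigrees from a template
#'
#' Stamps out `config$n_pedigrees` copies of the chosen template with
#' globally unique ids (`P<p>_I<k>`). Structure is deterministic: the seed
#' only affects downstream genotypes and phenotypes.
#'
#' @param config A [sim_config()].
#' @return A [pedigree()] tibble.
#' @export
build_pedigrees <- function(config) {
  tmpl <- switch(config$pedigree_template,
    sibship = ,
    nuclear = template_nuclear(config$template_size),
    three_generation = template_three_generation(),
    stop("unknown pedigree template: ", config$pedigree_template)
  )
  out <- purrr::map(seq_len(config$n_pedigrees), function(p) {
    relabel <- function(x) ifelse(is.na(x), NA_character_,
                                  sprintf("P%d_%s", p, x))
    tibble::tibble(
      pedigree_id = sprintf("P%d", p),
      individual_id = relabel(tmpl$individual_id),
      father_id = relabel(tmpl$father_id),
      mother_id = relabel(tmpl$mother_id),
      sex = tmpl$sex
    )
  })
  pedigree(dplyr::bind_rows(out))
}

# 2 founder parents + k full siblings (sexes alternate)
template_nuclear <- function(k) {
  tibble::tibble(
    individual_id = c("I1", "I2", sprintf("I%d", 2 + seq_len(k))),
    father_id = c(NA, NA, rep("I1", k)),
    mother_id = c(NA, NA, rep("I2", k)),
    sex = c("male", "female", rep(c("male", "female"), length.out = k))
  )
}

# Grandparent couple -> two children who each marry a founder spouse and
# have three children: 12 members, 3 generations.
template_three_generation <- function() {
  tibble::tibble(
    individual_id = c("I1", "I2", "I3", "I4", "I5", "I6",
                      "I7", "I8", "I9", "I10", "I11", "I12"),
    father_id = c(NA, NA, "I1", NA, "I1", NA,
                  "I3", "I3", "I3", "I6", "I6", "I6"),
    mother_id = c(NA, NA, "I2", NA, "I2", NA,
                  "I4", "I4", "I4", "I5", "I5", "I5"),
    sex = c("male", "female", "male", "female", "female", "male",
            "male", "female", "male", "female", "male", "female")
  )
}

# Generation depth (founders = 0), used to assign realistic baseline ages.
generation_depth <- function(ped) {
  depth <- setNames(rep(NA_real_, nrow(ped)), ped$individual_id)
  for (fid in unique(ped$pedigree_id)) {
    rows <- which(ped$pedigree_id == fid)
    ord <- topo_order_one(ped[rows, ], fid)
    for (j in ord) {
      r <- rows[j]
      pa <- c(ped$father_id[r], ped$mother_id[r])
      pa <- pa[!is.na(pa)]
      depth[ped$individual_id[r]] <-
        if (length(pa) == 0) 0 else max(depth[pa]) + 1
    }
  }
  depth
}
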
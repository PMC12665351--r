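# shared fixture builders; everything is generated in code

# one fully scored, well-formed session row
make_session <- function(sow_id = "s1", postures = c("LDS", "SIT", "STD"),
                         vocs = c("NONE", "SGT", NA, "SGT+LGT"),
                         st = 50, touches = 1,
                         intervention = "between_sites", group = "week1") {
  tibble::tibble(
    sow_id = sow_id,
    posture_1 = postures[1], posture_2 = postures[2],
    posture_3 = postures[3],
    voc_1 = vocs[1], voc_2 = vocs[2], voc_3 = vocs[3], voc_4 = vocs[4],
    shave_time_s = st, touches = touches,
    intervention_moment = intervention, hair_density = 2L,
    contemporary_group = group
  )
}

# small genotype object from an explicit dosage matrix
make_geno <- function(dosages, chrom = NULL, pos = NULL) {
  m <- ncol(dosages)
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- paste0("id", seq_len(nrow(dosages)))
  }
  genotypes(dosages, tibble::tibble(
    marker = paste0("m", seq_len(m)),
    chrom = chrom %||% rep("chr1", m),
    pos = pos %||% seq_len(m) * 1000
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# short chain settings for sampler unit tests
test_config <- function(iterations = 1600, burn_in = 500, thin = 10,
                        seed = 42, ...) {
  gibbs_config(iterations, burn_in, thin, seed = seed, ...)
}
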
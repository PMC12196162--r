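# Synthetic compound libraries with planted scaffold signal.
#
# Actives are lightly decorated variants of four large fused-ring cores
# (carbazole, acridine, dibenzofuran, xanthone, each carrying a fixed bulky
# side chain); because the shared core dominates the circular-fingerprint
# bit set, any two actives of one scaffold keep a Tanimoto similarity above
# 0.5 while remaining distinct structures. Negatives come from a disjoint
# set of small mono-ring / aliphatic scaffolds with a wider substituent
# alphabet. Every template x substituent combination is valence-correct by
# construction, and library difficulty is controlled by `scaffold_overlap`
# (fraction of negatives that carry an active scaffold) and `label_noise`
# (random label flips) rather than by feature geometry, so the same
# fixtures exercise fingerprints, descriptors and embeddings alike. No
# chemical realism (drug-likeness, ADMET) is attempted: only the
# statistical structure the pipeline assumes.

fixture_substituents <- function(class = c("active", "negative")) {
  class <- match.arg(class)
  if (class == "active") {
    c("C", "O", "N", "F", "Cl", "Br", "I", "S", "OC", "CC")
  } else {
    c("C", "CC", "CCC", "CCCC", "C(C)C", "C(C)(C)C", "O", "OC", "OCC", "N",
      "NC", "N(C)C", "F", "Cl", "Br", "I", "C#N", "C(=O)O", "C(=O)OC",
      "C(=O)N", "CO", "CCO", "C=C", "S", "SC")
  }
}

fixture_scaffolds <- function(class = c("active", "negative")) {
  class <- match.arg(class)
  if (class == "active") {
    c(carbazole    = "c1cc2c(cc1%s)n(CCOCCN3CCOCC3)c1cc(%s)ccc12",
      acridine     = "c1cc2nc3cc(%s)c(OCCN4CCCC4)cc3cc2cc1%s",
      dibenzofuran = "c1cc2c(cc1%s)oc1cc(%s)c(CN3CCN(C)CC3)cc12",
      xanthone     = "O=c1c2cc(%s)c(OCC(=O)N3CCOCC3)cc2oc2cc(%s)ccc12")
  } else {
    c(benzene      = "c1cc(%s)ccc1%s",
      pyridine     = "c1cc(%s)cnc1%s",
      furan        = "c1cc(%s)oc1%s",
      thiophene    = "c1cc(%s)sc1%s",
      pyrimidine   = "c1nc(%s)cc(%s)n1",
      cyclohexane  = "C1CC(%s)CCC1%s",
      piperidine   = "C1CC(%s)NCC1%s",
      pyrazole     = "c1cc(%s)n(%s)n1",
      pyrrole      = "c1cc(%s)n(%s)c1",
      oxane        = "C1CC(%s)OCC1%s",
      oxazole      = "c1oc(%s)nc1%s",
      cyclopentane = "C1CC(%s)CC1%s")
  }
}

# enumerate, canonicalize and de-duplicate the full decoration pool of a
# scaffold set; memoised per session since canonicalization dominates
fixture_pool <- function(scaffolds, class) {
  key <- paste0("pool|", paste(names(scaffolds), collapse = ","))
  if (!is.null(.seno$cache[[key]])) return(.seno$cache[[key]])
  subs <- fixture_substituents(class)
  grid <- expand.grid(s = names(scaffolds), a = subs, b = subs,
                      stringsAsFactors = FALSE)
  smi <- sprintf(scaffolds[grid$s], grid$a, grid$b)
  canon <- canonicalize(smi)
  keep <- !duplicated(canon)
  pool <- data.frame(smiles = smi[keep], canonical_smiles = canon[keep],
                     scaffold = grid$s[keep], stringsAsFactors = FALSE)
  .seno$cache[[key]] <- pool
  pool
}

#' Generate a synthetic labelled compound library
#'
#' Produces a labelled compound table with planted structure: actives share
#' a small set of fused-ring scaffolds, negatives are built from disjoint
#' templates except for a `scaffold_overlap` fraction that carries an active
#' scaffold (making the classes harder to separate), and `label_noise` flips
#' labels at random. With `label_noise = 0` and `scaffold_overlap = 0` a
#' scaffold-presence rule classifies the library perfectly.
#'
#' @param n_pos,n_neg class counts.
#' @param n_scaffolds number of distinct active scaffolds used (1-4).
#' @param label_noise probability in `[0, 1)` of flipping each label.
#' @param scaffold_overlap fraction in `[0, 1]` of negatives decorated from
#'   active scaffolds.
#' @param seed integer seed; identical seeds give identical tables.
#' @return data frame with columns `id`, `smiles`, `canonical_smiles`,
#'   `label`, `true_label`, `scaffold`, `provenance` (= "synthetic").
#' @export
generate_library <- function(n_pos = 111L, n_neg = 3951L, n_scaffolds = 4L,
                             label_noise = 0, scaffold_overlap = 0,
                             seed = 1L) {
  stopifnot(n_pos >= 1, n_neg >= 1, n_scaffolds >= 1,
            label_noise >= 0, label_noise < 1,
            scaffold_overlap >= 0, scaffold_overlap <= 1)
  act_sc <- fixture_scaffolds("active")
  if (n_scaffolds > length(act_sc)) {
    stop("at most ", length(act_sc), " active scaffolds available",
         call. = FALSE)
  }
  act_pool <- fixture_pool(act_sc[seq_len(n_scaffolds)], "active")
  neg_pool <- fixture_pool(fixture_scaffolds("negative"), "negative")

  n_overlap <- round(scaffold_overlap * n_neg)
  if (n_pos + n_overlap > nrow(act_pool)) {
    stop("infeasible spec: need ", n_pos + n_overlap,
         " active-scaffold structures but the pool holds ", nrow(act_pool),
         call. = FALSE)
  }
  if (n_neg - n_overlap > nrow(neg_pool)) {
    stop("infeasible spec: need ", n_neg - n_overlap,
         " negative-scaffold structures but the pool holds ", nrow(neg_pool),
         call. = FALSE)
  }

  withr::with_seed(seed, {
    act_idx <- sample.int(nrow(act_pool), n_pos + n_overlap)
    pos <- act_pool[act_idx[seq_len(n_pos)], ]
    neg_from_act <- act_pool[act_idx[seq_len(n_overlap) + n_pos], ]
    neg <- rbind(neg_from_act,
                 neg_pool[sample.int(nrow(neg_pool), n_neg - n_overlap), ])
    lib <- rbind(cbind(pos, true_label = 1L), cbind(neg, true_label = 0L))
    lib$label <- lib$true_label
    if (label_noise > 0) {
      flip <- runif(nrow(lib)) < label_noise
      lib$label[flip] <- 1L - lib$label[flip]
    }
    lib$id <- sprintf("CPD%05d", seq_len(nrow(lib)))
    lib$provenance <- "synthetic"
    rownames(lib) <- NULL
    lib[, c("id", "smiles", "canonical_smiles", "label", "true_label",
            "scaffold", "provenance")]
  })
}

#' Generate a compound-to-source annotation map
#'
#' Assigns every compound to a source (e.g. a medicinal herb), optionally
#' planting one source with an exactly specified member set, to exercise the
#' enrichment module. Non-planted compounds are assigned uniformly at
#' random; every compound receives exactly one source, planted members
#' receive exactly the planted source.
#'
#' @param compound_ids character vector of compound ids.
#' @param n_sources number of random sources.
#' @param planted optional `list(source = <name>, members = <ids>)`.
#' @param seed integer seed.
#' @return data frame with columns `compound_id`, `source`, `family`,
#'   `genus` (random sources are grouped into synthetic families/genera).
#' @export
generate_source_map <- function(compound_ids, n_sources = 20L,
                                planted = NULL, seed = 1L) {
  stopifnot(n_sources >= 1)
  compound_ids <- as.character(compound_ids)
  planted_ids <- character(0)
  if (!is.null(planted)) {
    stopifnot(is.list(planted), !is.null(planted$source),
              !is.null(planted$members))
    planted_ids <- as.character(planted$members)
    if (!all(planted_ids %in% compound_ids)) {
      stop("planted members must be a subset of compound_ids", call. = FALSE)
    }
  }
  rest <- setdiff(compound_ids, planted_ids)
  src_names <- sprintf("Herb%03d", seq_len(n_sources))
  withr::with_seed(seed, {
    assigned <- sample(src_names, length(rest), replace = TRUE)
  })
  map <- data.frame(compound_id = rest, source = assigned,
                    stringsAsFactors = FALSE)
  if (length(planted_ids)) {
    map <- rbind(map, data.frame(compound_id = planted_ids,
                                 source = planted$source,
                                 stringsAsFactors = FALSE))
  }
  src_all <- sort(unique(map$source))
  fam <- stats::setNames(sprintf("Family%02d",
                                 (seq_along(src_all) - 1L) %/% 3L + 1L),
                         src_all)
  gen <- stats::setNames(sprintf("Genus%03d", seq_along(src_all)), src_all)
  map$family <- unname(fam[map$source])
  map$genus <- unname(gen[map$source])
  rownames(map) <- NULL
  map
}
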
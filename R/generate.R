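#' Parameters for the synthetic fluorochemical generator
#'
#' Defaults describe a plausible registry slice of small fluorochemicals:
#' mostly aliphatic scaffolds of 3-10 carbons with per-site fluorination
#' probability high enough that the generated library spans the 30%
#' fluorine-fraction threshold from both sides, a minority of ethers and
#' aromatics, occasional chlorination, and ~10% two-component records
#' (mixtures/salt-like).
#'
#' @param p_f Probability that any substitutable site carries fluorine.
#' @param p_cl Probability of chlorine at a site (evaluated after fluorine).
#' @param p_br Probability of bromine at a site.
#' @param chain_range Length-2 integer range of backbone carbons.
#' @param scaffold_weights Named weights for `linear`, `branched`, `ether`,
#'   `aromatic` scaffolds.
#' @param p_second_component Probability of appending a second, independently
#'   generated fragment (a multicomponent record).
#' @param perfluorinate If TRUE every substitutable site is fluorinated and
#'   aromatic scaffolds are disabled — every molecule then contains a fully
#'   fluorinated carbon by construction.
#' @return A list of class `synthesis_params`.
#' @export
synthesis_params <- function(p_f = 0.45, p_cl = 0.05, p_br = 0.01,
                             chain_range = c(3L, 10L),
                             scaffold_weights = c(linear = 0.40,
                                                  branched = 0.25,
                                                  ether = 0.20,
                                                  aromatic = 0.15),
                             p_second_component = 0.10,
                             perfluorinate = FALSE) {
  stopifnot(p_f >= 0, p_f <= 1, p_cl >= 0, p_cl <= 1, p_br >= 0, p_br <= 1,
            p_f + p_cl + p_br <= 1 + 1e-9,
            length(chain_range) == 2L, chain_range[1] >= 2L,
            chain_range[2] >= chain_range[1],
            all(c("linear", "branched", "ether", "aromatic") %in%
                  names(scaffold_weights)),
            p_second_component >= 0, p_second_component <= 1)
  structure(list(p_f = p_f, p_cl = p_cl, p_br = p_br,
                 chain_range = as.integer(chain_range),
                 scaffold_weights = scaffold_weights,
                 p_second_component = p_second_component,
                 perfluorinate = perfluorinate),
            class = "synthesis_params")
}

with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate seeded synthetic fluorinated molecules
#'
#' Builds `n` random fluorochemical SMILES from simple scaffolds (linear and
#' branched alkanes, aliphatic ethers, benzene rings with an alkyl tail) with
#' per-site halogenation. Alongside each SMILES the generator records
#' construction-time ground truth counted directly while assembling the
#' molecule — heavy-atom, fluorine and hydrogen tallies and the resulting
#' fluorine fraction — which is deliberately independent of the package's
#' formula pipeline so the two can be cross-checked.
#'
#' @param n Number of molecules.
#' @param seed Integer seed; identical seed + params give identical output.
#' @param params A [synthesis_params()] object.
#' @return A tibble: `id`, `smiles`, `scaffold`, `n_components`,
#'   `meta_n_heavy`, `meta_n_f`, `meta_n_h`, `meta_pct_f_excl_h` (percent,
#'   from the construction-time tallies).
#' @examples
#' generate_fluorochemicals(5, seed = 1)
#' @export
generate_fluorochemicals <- function(n, seed, params = synthesis_params()) {
  stopifnot(n >= 1L, inherits(params, "synthesis_params"))
  with_preserved_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      frag <- random_fragment(params)
      n_comp <- 1L
      if (stats::runif(1) < params$p_second_component) {
        frag2 <- random_fragment(params)
        frag <- list(
          smiles = paste0(frag$smiles, ".", frag2$smiles),
          scaffold = paste(frag$scaffold, frag2$scaffold, sep = "+"),
          n_heavy = frag$n_heavy + frag2$n_heavy,
          n_f = frag$n_f + frag2$n_f,
          n_h = frag$n_h + frag2$n_h
        )
        n_comp <- 2L
      }
      tibble::tibble(
        id = sprintf("syn_%04d", i),
        smiles = frag$smiles,
        scaffold = frag$scaffold,
        n_components = n_comp,
        meta_n_heavy = frag$n_heavy,
        meta_n_f = frag$n_f,
        meta_n_h = frag$n_h,
        meta_pct_f_excl_h = 100 * frag$n_f / frag$n_heavy
      )
    })
    dplyr::bind_rows(rows)
  })
}

# one connected fragment + exact atom bookkeeping
random_fragment <- function(params) {
  w <- params$scaffold_weights
  if (params$perfluorinate) w["aromatic"] <- 0
  scaffold <- sample(names(w), 1L, prob = w)
  switch(scaffold,
    linear = random_chain(params, branched = FALSE),
    branched = random_chain(params, branched = TRUE),
    ether = random_chain(params, branched = FALSE, ether = TRUE),
    aromatic = random_aromatic(params)
  )
}

sample_site <- function(params, k) {
  # k independent substituent sites -> "F", "Cl", "Br" or "" (hydrogen)
  if (params$perfluorinate) return(rep("F", k))
  u <- stats::runif(k)
  ifelse(u < params$p_f, "F",
         ifelse(u < params$p_f + params$p_cl, "Cl",
                ifelse(u < params$p_f + params$p_cl + params$p_br, "Br", "")))
}

# draw one element of x (unlike sample(x, 1), never treats a scalar as 1:x)
draw_one <- function(x) x[[sample.int(length(x), 1L)]]

random_chain <- function(params, branched = FALSE, ether = FALSE) {
  len <- draw_one(seq(params$chain_range[1], params$chain_range[2]))
  # positions of non-carbon backbone atom (ether oxygen) / branch attachment
  o_pos <- if (ether && len >= 3L) draw_one(2:(len - 1L)) else 0L
  branch_pos <- if (branched && len >= 3L) draw_one(2:(len - 1L)) else 0L
  tokens <- character(len)
  n_heavy <- 0L; n_f <- 0L; n_h <- 0L
  for (i in seq_len(len)) {
    if (i == o_pos) {
      tokens[i] <- "O"
      n_heavy <- n_heavy + 1L
      next
    }
    free <- if (i == 1L || i == len) 3L else 2L
    branch_here <- branched && i == branch_pos
    if (branch_here) free <- free - 1L
    subs <- sample_site(params, free)
    n_heavy <- n_heavy + 1L + sum(subs != "")
    n_f <- n_f + sum(subs == "F")
    n_h <- n_h + sum(subs == "")
    sub_txt <- paste0(vapply(subs[subs != ""], function(s) paste0("(", s, ")"),
                             character(1)), collapse = "")
    br_txt <- ""
    if (branch_here) {
      bsubs <- sample_site(params, 3L)
      n_heavy <- n_heavy + 1L + sum(bsubs != "")
      n_f <- n_f + sum(bsubs == "F")
      n_h <- n_h + sum(bsubs == "")
      br_txt <- paste0("(C", paste0(vapply(bsubs[bsubs != ""],
                                           function(s) paste0("(", s, ")"),
                                           character(1)), collapse = ""), ")")
    }
    tokens[i] <- paste0("C", sub_txt, br_txt)
  }
  list(smiles = paste0(tokens, collapse = ""),
       scaffold = if (ether) "ether" else if (branched) "branched" else "linear",
       n_heavy = n_heavy, n_f = n_f, n_h = n_h)
}

random_aromatic <- function(params) {
  # benzene ring; each of the six positions carries H or a sampled halogen,
  # one position may carry a short alkyl tail instead
  subs <- sample_site(params, 6L)
  tail_pos <- draw_one(0:6)
  n_heavy <- 6L; n_f <- 0L; n_h <- 0L
  ring <- character(6)
  for (i in 1:6) {
    if (i == tail_pos) {
      tsubs <- sample_site(params, 3L)
      n_heavy <- n_heavy + 1L + sum(tsubs != "")
      n_f <- n_f + sum(tsubs == "F")
      n_h <- n_h + sum(tsubs == "")
      ring[i] <- paste0("c(C", paste0(vapply(tsubs[tsubs != ""],
                                             function(s) paste0("(", s, ")"),
                                             character(1)), collapse = ""), ")")
    } else if (subs[i] != "") {
      n_heavy <- n_heavy + 1L
      n_f <- n_f + (subs[i] == "F")
      ring[i] <- paste0("c(", subs[i], ")")
    } else {
      n_h <- n_h + 1L
      ring[i] <- "c"
    }
  }
  smiles <- paste0(sub("^c", "c1", ring[1]),
                   paste0(ring[2:5], collapse = ""),
                   sub("^c", "c1", ring[6]))
  list(smiles = smiles, scaffold = "aromatic",
       n_heavy = n_heavy, n_f = n_f, n_h = n_h)
}

#' Generate random molecular-formula strings
#'
#' Seeded generator of Hill-notation formula strings over a small element
#' pool, used for property-based testing of the formula metrics.
#'
#' @param n Number of formulas.
#' @param seed Integer seed.
#' @return Character vector of formula strings.
#' @export
generate_formulas <- function(n, seed) {
  with_preserved_seed(seed, {
    pool <- c("C", "H", "F", "O", "N", "S", "Cl", "Na", "Br", "Si")
    vapply(seq_len(n), function(i) {
      k <- sample(1:6, 1L)
      elems <- sample(pool, k)
      counts <- sample(1:20, k, replace = TRUE)
      paste0(elems, ifelse(counts > 1L, counts, ""), collapse = "")
    }, character(1))
  })
}
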
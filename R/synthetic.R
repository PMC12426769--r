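# Synthetic reaction corpora with known substrate-to-condition rules.
#
# Commercial patent-reaction corpora cannot be redistributed, so the package
# manufactures document-grouped corpora whose latent generative rules are
# known: each reaction class holds two (or more) substrate families realized
# as distinct scaffold series, and each (class, family) pair has its own
# agent set, temperature and equivalence-ratio targets. Because conditions
# are substrate-dependent within a class, a learned model that reads the
# reaction fingerprint can beat the class-popularity baseline -- the property
# the corpus exists to probe. Recovery of the rules is verifiable through
# `world_ground_truth()`.

# Built-in table of real small-molecule agents (common solvents, bases,
# catalysts, ligands, acids, reagents), grouped by the stoichiometric regime
# in which each is typically used. All entries parse under OpenBabel and are
# canonically distinct.
.builtin_agents <- function() {
  solvent <- c(
    "O", "CO", "CCO", "CC(C)O", "CCCCO", "CC(C)=O", "CCOC(C)=O", "C1CCOC1",
    "COCCOC", "C1COCCO1", "CCOCC", "COC(C)(C)C", "CN(C)C=O", "CC(=O)N(C)C",
    "CN1CCCC1=O", "CS(C)=O", "CC#N", "ClCCl", "ClC(Cl)Cl", "ClCCCl",
    "c1ccccc1", "Cc1ccccc1", "Cc1ccccc1C", "CCCCCC", "C1CCCCC1", "CCCCC",
    "CCCCCCC", "COCCO", "OCCO", "CC(C)(C)O", "COc1ccccc1")
  stoich <- c(
    "[Na+].[OH-]", "[K+].[OH-]", "[Li+].[OH-]", "O=C([O-])[O-].[K+].[K+]",
    "O=C([O-])[O-].[Na+].[Na+]", "O=C([O-])[O-].[Cs+].[Cs+]",
    "OC(=O)[O-].[Na+]", "[K+].[K+].[K+].[O-]P([O-])([O-])=O", "[H-].[Na+]",
    "CC(C)(C)[O-].[K+]", "C[O-].[Na+]", "CC[O-].[Na+]",
    "CC(C)[N-]C(C)C.[Li+]", "CCCC[Li]", "CCN(CC)CC", "CCN(C(C)C)C(C)C",
    "c1ccncc1", "c1c[nH]cn1", "CC(=O)[O-].[Na+]", "[F-].[K+]", "[F-].[Cs+]",
    "NCCO", "CNC", "CCNCC",
    "Cl", "Br", "OS(O)(=O)=O", "O[N+]([O-])=O", "OP(O)(O)=O", "CC(O)=O",
    "OC(=O)C(F)(F)F", "Cc1ccc(S(O)(=O)=O)cc1", "CS(O)(=O)=O", "OC=O",
    "[BH4-].[Na+]", "[AlH4-].[Li+]", "[H][H]", "CC(C)C[Al]CC(C)C",
    "[BH3-]C#N.[Na+]", "O=[Mn]=O", "OO", "O=C(OO)c1cccc(Cl)c1", "O=S(Cl)Cl",
    "O=C(Cl)C(Cl)=O", "O=P(Cl)(Cl)Cl", "CC(=O)OC(C)=O",
    "CC(C)(C)OC(=O)OC(=O)OC(C)(C)C", "CCN=C=NCCCN(C)C",
    "C1CCCCC1N=C=NC2CCCCC2", "O=C1CCC(=O)N1Br", "O=C1CCC(=O)N1I", "II",
    "C[Si](C)(C)Cl", "CI", "[NH4+].[Cl-]", "[Li+].[Cl-]",
    "[N-]=[N+]=[N-].[Na+]", "NN", "N", "[Na+].[O-]N=O",
    "C[Si](C)(C)OS(=O)(=O)C(F)(F)F", "CC(C)(C)[Si](C)(C)Cl", "ClCBr",
    "BrCCBr")
  catalytic <- c(
    "[Pd]", "[Pt]", "[Ni]", "[Rh]", "[Ru]", "[Cu]I", "Br[Cu]",
    "CC(=O)O[Pd]OC(C)=O", "CC(=O)O[Cu]OC(C)=O", "Cl[Fe](Cl)Cl", "Cl[Zn]Cl",
    "[Zn]", "[Mg]", "[Fe]", "Cl[Al](Cl)Cl", "Cl[Ti](Cl)(Cl)Cl", "Cl[Sn]Cl",
    "O=[Pt]=O",
    "c1ccc(P(c2ccccc2)c3ccccc3)cc1", "C1CCC(P(C2CCCCC2)C3CCCCC3)CC1",
    "c1ccc(-c2ccccn2)nc1", "c1ccc2c(c1)ccc1cccnc12",
    "CN(C)c1ccncc1")
  data.frame(
    smiles = c(solvent, stoich, catalytic),
    regime = c(rep("solvent", length(solvent)),
               rep("stoich", length(stoich)),
               rep("catalytic", length(catalytic))),
    stringsAsFactors = FALSE)
}

# Scaffold cores: each entry is a (reactant template, product template) pair
# with an "X" substituent slot; distinct cores give fingerprint-separable
# substrate families while the substituent series gives in-family variety.
.scaffold_cores <- function() {
  list(
    list(r = "Brc1ccc(X)cc1",     p = "c1ccc(-c2ccc(X)cc2)cc1"),
    list(r = "Clc1ccc(X)cc1",     p = "c1ccc(-c2ccc(X)cc2)nc1"),
    list(r = "Ic1ccc(X)cc1",      p = "C(#Cc1ccccc1)c1ccc(X)cc1"),
    list(r = "Brc1ccc(X)s1",      p = "c1ccc(-c2ccc(X)s2)cc1"),
    list(r = "O=Cc1ccc(X)cc1",    p = "OCc1ccc(X)cc1"),
    list(r = "CC(=O)c1ccc(X)cc1", p = "CC(O)c1ccc(X)cc1"),
    list(r = "N#Cc1ccc(X)cc1",    p = "NCc1ccc(X)cc1"),
    list(r = "O=C(O)c1ccc(X)cc1", p = "COC(=O)c1ccc(X)cc1"),
    list(r = "Brc1cccc(X)c1",     p = "OB(O)c1cccc(X)c1"),
    list(r = "O=Cc1cccc(X)c1",    p = "OC(CC(C)=O)c1cccc(X)c1"))
}

.scaffold_substituents <- function() c("C", "CC", "CCC", "OC", "OCC", "F")

.co_reactants <- function() {
  c("OB(O)c1ccccc1", "C=Cc1ccccc1", "C#Cc1ccccc1", "Nc1ccccc1",
    "OCc1ccccc1", "CC(=O)Cl", "BrCC=C", "OCCN")
}

.temperature_peaks <- function() c(-78, 0, 25, 85, 115)
.coreactant_eq_targets <- function() c(1.1, 1.5, 2.0, 2.5)

#' Configuration of a synthetic reaction world
#'
#' Defaults describe the reference study conditions used throughout the
#' package: 4 reaction classes, 2 substrate families per class, a
#' 24-agent vocabulary, 5\% agent-swap label noise, 5 degC temperature
#' jitter and 2\% multiplicative amount jitter, with 5 records per
#' document.
#'
#' @param n_classes number of reaction classes.
#' @param families_per_class substrate families per class (>= 2 makes
#'   conditions substrate-dependent within a class).
#' @param vocab_size number of vocabulary agents drawn from the built-in
#'   table (at most the table size, 118).
#' @param agent_swap_prob probability that one agent of a record is swapped
#'   for a random vocabulary member (label noise).
#' @param temperature_jitter_sd Gaussian jitter on temperature, degC.
#' @param amount_jitter_frac multiplicative lognormal-ish jitter fraction on
#'   equivalence ratios.
#' @param records_per_document records per synthetic document (documents are
#'   contiguous blocks).
#' @param seed integer seed fixing the world (rules, vocabulary).
#' @return a `world_config` list.
#' @export
world_config <- function(n_classes = 4L, families_per_class = 2L,
                         vocab_size = 24L, agent_swap_prob = 0.05,
                         temperature_jitter_sd = 5,
                         amount_jitter_frac = 0.02,
                         records_per_document = 5L, seed = 1L) {
  stopifnot(n_classes >= 1L, families_per_class >= 1L, vocab_size >= 6L,
            agent_swap_prob >= 0, agent_swap_prob <= 1,
            temperature_jitter_sd >= 0, amount_jitter_frac >= 0,
            records_per_document >= 1L)
  structure(list(n_classes = as.integer(n_classes),
                 families_per_class = as.integer(families_per_class),
                 vocab_size = as.integer(vocab_size),
                 agent_swap_prob = agent_swap_prob,
                 temperature_jitter_sd = temperature_jitter_sd,
                 amount_jitter_frac = amount_jitter_frac,
                 records_per_document = as.integer(records_per_document),
                 seed = as.integer(seed)),
            class = "world_config")
}

#' Generate a synthetic world
#'
#' Draws the agent vocabulary from the built-in table (balanced across the
#' solvent / stoichiometric / catalytic regimes), assigns each (class,
#' family) pair a distinct scaffold series and a condition rule (agent set,
#' temperature mean from the empirical peaks -78/0/25/85/115 degC,
#' co-reactant equivalence target from 1.1/1.5/2.0/2.5, role-dependent agent
#' equivalence targets). Families of the same class always differ in at
#' least one agent. Deterministic for a fixed config.
#'
#' @param cfg a [world_config()].
#' @return an object of class `synthetic_world`.
#' @export
generate_world <- function(cfg = world_config()) {
  stopifnot(inherits(cfg, "world_config"))
  tab <- .builtin_agents()
  if (cfg$vocab_size > nrow(tab)) {
    stop("vocab_size ", cfg$vocab_size, " exceeds built-in agent table (",
         nrow(tab), ")")
  }
  cores <- .scaffold_cores()
  n_fam_total <- cfg$n_classes * cfg$families_per_class
  with_seed(cfg$seed, {
    # vocabulary balanced across regimes so rules can span all three
    per <- max(2L, floor(cfg$vocab_size / 3))
    pick <- function(regime, k) {
      pool <- tab$smiles[tab$regime == regime]
      sample(pool, min(k, length(pool)))
    }
    vsmiles <- c(pick("solvent", per), pick("stoich", per),
                 pick("catalytic", per))
    extra <- cfg$vocab_size - length(vsmiles)
    if (extra > 0L) {
      pool <- setdiff(tab$smiles, vsmiles)
      vsmiles <- c(vsmiles, sample(pool, extra))
    }
    vocab <- agent_vocabulary(vsmiles)
    regime_of <- stats::setNames(tab$regime, canonicalize_smiles(tab$smiles))
    vregime <- unname(regime_of[vocab$agents])

    core_order <- sample(length(cores))
    subs <- .scaffold_substituents()
    co_pool <- .co_reactants()

    rules <- vector("list", cfg$n_classes)
    scaffold_rows <- list()
    for (cl in seq_len(cfg$n_classes)) {
      class_id <- sprintf("%d.%d.%d", cl, cl, cl)
      co <- co_pool[((cl - 1L) %% length(co_pool)) + 1L]
      fam_rules <- vector("list", cfg$families_per_class)
      seen_sets <- list()
      for (fm in seq_len(cfg$families_per_class)) {
        core_idx <- core_order[(((cl - 1L) * cfg$families_per_class + fm - 1L) %%
                                  length(cores)) + 1L]
        core <- cores[[core_idx]]
        repeat {
          n_agents <- sample(2:3, 1L)
          ag <- character(0)
          targets <- numeric(0)
          st <- sample(vocab$agents[vregime == "stoich"], 1L)
          ag <- c(ag, st)
          targets <- c(targets, sample(c(1.0, 1.2, 1.5, 2.0, 2.5), 1L))
          sv <- sample(vocab$agents[vregime == "solvent"], 1L)
          ag <- c(ag, sv)
          # solvent-scale loadings; values sit strictly inside amount
          # bins so the noiseless limit is robust to roundoff
          targets <- c(targets, sample(c(12, 15, 25, 30), 1L))
          if (n_agents >= 3L) {
            ct <- sample(vocab$agents[vregime == "catalytic"], 1L)
            ag <- c(ag, ct)
            targets <- c(targets, sample(c(0.005, 0.012, 0.03, 0.07), 1L))
          }
          key <- paste(sort(ag), collapse = "|")
          if (!key %in% unlist(seen_sets)) break
        }
        seen_sets <- c(seen_sets, key)
        names(targets) <- ag
        fam_rules[[fm]] <- list(
          class_id = class_id,
          family = fm,
          agents = ag,
          agent_eq_targets = targets,
          temperature_mean = sample(.temperature_peaks(), 1L),
          coreactant_eq_target = sample(.coreactant_eq_targets(), 1L),
          core = core)
        for (s in subs) {
          scaffold_rows[[length(scaffold_rows) + 1L]] <- data.frame(
            reactant = canonicalize_smiles(gsub("X", s, core$r, fixed = TRUE)),
            product = canonicalize_smiles(gsub("X", s, core$p, fixed = TRUE)),
            class = cl, family = fm, stringsAsFactors = FALSE)
        }
      }
      rules[[cl]] <- list(class_id = class_id, co_reactant = co,
                          families = fam_rules)
    }
    scaffolds <- do.call(rbind, scaffold_rows)
    structure(list(cfg = cfg, vocab = vocab, rules = rules,
                   scaffolds = scaffolds,
                   class_ids = vapply(rules, `[[`, character(1), "class_id")),
              class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic world:", x$cfg$n_classes, "classes x",
      x$cfg$families_per_class, "families,",
      length(x$vocab), "vocabulary agents,",
      nrow(x$scaffolds), "scaffolds\n")
  invisible(x)
}

#' Sample reaction records from a synthetic world
#'
#' Each record picks a class, family and scaffold uniformly; the limiting
#' reactant's molar amount is log-uniform in \[1e-4, 1e-1\] mol, the
#' co-reactant and agent amounts follow the family rule times the amount
#' jitter, the temperature is the rule mean plus Gaussian jitter, and with
#' probability `agent_swap_prob` one agent is swapped for a random
#' vocabulary member. Records are grouped into contiguous synthetic
#' documents.
#'
#' @param world a [generate_world()] result.
#' @param n number of records.
#' @param seed sampling seed (independent of the world seed).
#' @param document_prefix prefix for synthetic document ids.
#' @return list of [reaction_record()]s.
#' @export
sample_records <- function(world, n, seed = 1L, document_prefix = "doc") {
  stopifnot(inherits(world, "synthetic_world"), n >= 1L)
  cfg <- world$cfg
  with_seed(seed, {
    records <- vector("list", n)
    for (i in seq_len(n)) {
      cl <- sample.int(cfg$n_classes, 1L)
      fm <- sample.int(cfg$families_per_class, 1L)
      rule <- world$rules[[cl]]$families[[fm]]
      sc <- world$scaffolds[world$scaffolds$class == cl &
                              world$scaffolds$family == fm, ]
      row <- sc[sample.int(nrow(sc), 1L), ]
      jitter <- function(k) {
        if (cfg$amount_jitter_frac == 0) rep(1, k)
        else exp(stats::rnorm(k, 0, cfg$amount_jitter_frac))
      }
      lim_moles <- 10^stats::runif(1, -4, -1)
      co_moles <- lim_moles * rule$coreactant_eq_target * jitter(1)
      agents_smi <- rule$agents
      if (cfg$agent_swap_prob > 0 &&
          stats::runif(1) < cfg$agent_swap_prob) {
        pos <- sample.int(length(agents_smi), 1L)
        repl_pool <- setdiff(world$vocab$agents, agents_smi)
        agents_smi[pos] <- sample(repl_pool, 1L)
      }
      # amounts follow the rule targets of the slots, even for a swapped agent
      agent_moles <- lim_moles * unname(rule$agent_eq_targets) *
        jitter(length(agents_smi))
      temp <- rule$temperature_mean +
        if (cfg$temperature_jitter_sd > 0)
          stats::rnorm(1, 0, cfg$temperature_jitter_sd) else 0
      # reactant order randomized so nothing downstream can rely on it
      reactants <- list(list(smiles = row$reactant, moles = lim_moles),
                        list(smiles = world$rules[[cl]]$co_reactant,
                             moles = co_moles))
      if (stats::runif(1) < 0.5) reactants <- rev(reactants)
      doc <- sprintf("%s%06d", document_prefix,
                     ((i - 1L) %/% cfg$records_per_document) + 1L)
      records[[i]] <- reaction_record(
        document_id = doc,
        reactants = reactants,
        agents = Map(function(s, m) list(smiles = s, moles = m),
                     agents_smi, agent_moles),
        products = list(list(smiles = row$product)),
        temperature_c = temp,
        class_id = world$rules[[cl]]$class_id,
        canonicalize = TRUE)
    }
    records
  })
}

# Identify the (class, family) of a record by scaffold membership.
.locate_family <- function(world, record) {
  rsmis <- .side_smiles(record$reactants)
  pool <- world$scaffolds
  if (!is.na(record$class_id) && record$class_id %in% world$class_ids) {
    pool <- pool[pool$class == match(record$class_id, world$class_ids), ]
  }
  hit <- pool[pool$reactant %in% rsmis, ]
  if (nrow(hit) == 0L) {
    stop("record is foreign to this world: no reactant matches a scaffold")
  }
  hit[1L, c("class", "family")]
}

#' Noiseless ground-truth conditions for a world record
#'
#' Returns the rule conditions of the record's (class, family), binned with
#' the supplied schemes -- i.e. what the record's conditions would be with
#' all noise rates at zero. Errors for records not generated by this world.
#'
#' @param world a [generate_world()] result.
#' @param record a [reaction_record()] sampled from `world`.
#' @param schemes bin schemes, as from [default_bin_schemes()].
#' @return a [condition_set()] (per-stage confidences set to 1).
#' @export
world_ground_truth <- function(world, record,
                               schemes = default_bin_schemes()) {
  loc <- .locate_family(world, record)
  rule <- world$rules[[loc$class]]$families[[loc$family]]
  scaffold_set <- world$scaffolds$reactant[world$scaffolds$class == loc$class &
                                             world$scaffolds$family == loc$family]
  rsmis <- .side_smiles(record$reactants)
  r_eq <- ifelse(rsmis %in% scaffold_set, 1.0, rule$coreactant_eq_target)
  agent_idx <- sort(vocab_index(world$vocab, rule$agents))
  agent_smis <- world$vocab$agents[agent_idx]
  eq_of <- rule$agent_eq_targets[agent_smis]
  condition_set(
    agents = agent_idx,
    temperature_bin = assign_bin(rule$temperature_mean, schemes$temperature),
    reactant_bins = assign_bin(r_eq, schemes$reactant_amount),
    agent_bins = stats::setNames(assign_bin(unname(eq_of),
                                            schemes$agent_amount), agent_smis),
    confidences = c(1, 1, 1, 1), score = 1)
}
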
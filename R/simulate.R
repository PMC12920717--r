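#' Simulation parameters for a synthetic HSC cohort
#'
#' Defaults describe a realistic colony-sequencing design: a few hundred
#' sampled HSC lineages that diversified within the first weeks of
#' embryogenesis, clock-like accumulation of ~17 single-nucleotide
#' alterations per lineage per year, and clonal-hematopoiesis (CH) founding
#' events arriving as an inhomogeneous Poisson process whose rate grows
#' exponentially with age.  Each CH event instantaneously converts a clade
#' of primary lineages; the clade's share of the sampled lineages is drawn
#' from a Beta distribution.
#'
#' @param n_lineages sampled HSC tips (default 300).
#' @param mutation_rate SNAs per lineage per year (default 17).
#' @param embryonic_window years over which the initial diversification into
#'   `n_lineages` lineages occurs (default 0.1).
#' @param ch_rate baseline CH founding rate per lineage-year at age 0
#'   (default 3e-5).
#' @param ch_age_coef exponential age-dependence of the CH rate, per year
#'   (default 0.05); the instantaneous whole-individual rate at age t is
#'   `n_lineages * ch_rate * exp(ch_age_coef * t)`.  Set to 0 for a
#'   constant-rate process.
#' @param clade_shape1,clade_shape2 Beta parameters of the converted clade
#'   fraction (defaults 1 and 9: mean 10%, right-skewed); realized sizes are
#'   at least 2 lineages.
#' @param expansion_window years over which a founded clade's internal
#'   splits are laid down (default 0.05: expansion is effectively
#'   instantaneous on the lifespan scale).
#' @param vaf_threshold tip-variant threshold the ground-truth decay is
#'   reported at (default 0.01).  Tip variants are below this threshold by
#'   construction only when `n_lineages >= 1 / (2 * vaf_threshold)`; a
#'   warning is raised otherwise.
#' @return An object of class `"sim_params"`.
#' @export
sim_params <- function(n_lineages = 300L, mutation_rate = 17,
                       embryonic_window = 0.1, ch_rate = 3e-5,
                       ch_age_coef = 0.05, clade_shape1 = 1,
                       clade_shape2 = 9, expansion_window = 0.05,
                       vaf_threshold = 0.01) {
  if (n_lineages < 2) stop_input("n_lineages must be >= 2")
  if (mutation_rate <= 0) stop_input("mutation_rate must be > 0")
  if (ch_rate < 0) stop_input("ch_rate must be >= 0")
  if (n_lineages < 1 / (2 * vaf_threshold))
    warning(sprintf(paste0("n_lineages = %d puts tip variants at VAF %.4g, at or above the ",
                           "threshold %g: tip variants will not be excluded by the filter"),
                    n_lineages, 0.5 / n_lineages, vaf_threshold), call. = FALSE)
  structure(list(n_lineages = as.integer(n_lineages),
                 mutation_rate = mutation_rate,
                 embryonic_window = embryonic_window,
                 ch_rate = ch_rate, ch_age_coef = ch_age_coef,
                 clade_shape1 = clade_shape1, clade_shape2 = clade_shape2,
                 expansion_window = expansion_window,
                 vaf_threshold = vaf_threshold),
            class = "sim_params")
}

#' Simulate one individual's HSC phylogeny, genotypes and VFS
#'
#' Forward-simulates the life history of a sampled HSC population:
#' `n_lineages` primary lineages split within the embryonic window (emitted
#' as a caterpillar of near-zero internal branches, so the tree stays
#' strictly binary); CH founding events drop on the lifespan according to
#' the age-dependent Poisson process; each event converts a clade of the
#' drawn size, replacing primary lineages; mutations accrue on every branch
#' as Poisson(`mutation_rate` x branch years).  The variant spectrum follows
#' from the tree: a mutation on a branch subtending k of n tips has cell
#' fraction k/n and VAF k/(2n).
#'
#' @param age individual's age in years (>= 0); all tips end at this age.
#' @param params a [sim_params()] object.
#' @param seed integer seed; output is deterministic given `(age, params,
#'   seed)`.
#' @param forced_events optional data.frame with columns `time` and `size`
#'   forcing specific CH events instead of drawing them (sizes in lineages).
#' @param genotype build the sparse lineages-by-variants genotype matrix
#'   (can be large for old individuals; `FALSE` skips it).
#' @param sample_id sample identifier for the emitted VFS.
#' @return Object of class `"sim_individual"`: list with `age`, `tree` (an
#'   `"hsc_tree"`: `phylo` + per-branch mutation table), `matrix` (sparse
#'   genotype matrix or `NULL`), `vfs` (colony-cell VFS, unfiltered),
#'   `true_decay` (ground-truth decay at `params$vaf_threshold`),
#'   `ch_events`, and an event log.
#' @export
simulate_individual <- function(age, params = sim_params(), seed = 1L,
                                forced_events = NULL, genotype = TRUE,
                                sample_id = "sim") {
  stopifnot(inherits(params, "sim_params"))
  if (!is.numeric(age) || length(age) != 1 || age < 0)
    stop_input("age must be a single non-negative number")
  set.seed(seed)
  n <- params$n_lineages
  ew <- if (age > 0) min(params$embryonic_window, age / 2) else 0
  c0 <- params$ch_age_coef
  log_lines <- character()

  draw_size <- function(k) pmax(2L, as.integer(round(
    rbeta(k, params$clade_shape1, params$clade_shape2) * n)))

  if (is.null(forced_events)) {
    lam <- if (c0 > 0) n * params$ch_rate * (exp(c0 * age) - 1) / c0
           else n * params$ch_rate * age
    ne <- rpois(1, lam)
    if (ne > 0) {
      u <- runif(ne)
      tf <- if (c0 > 0) log(1 + u * (exp(c0 * age) - 1)) / c0 else u * age
      tf <- sort(pmin(pmax(tf, ew + 1e-6), age * (1 - 1e-9)))
      sz <- draw_size(ne)
    } else { tf <- numeric(); sz <- integer() }
  } else {
    if (any(forced_events$time <= ew) || any(forced_events$time >= age))
      stop_input("forced event times must lie in (embryonic_window, age)")
    ord <- order(forced_events$time)
    tf <- forced_events$time[ord]
    sz <- as.integer(forced_events$size[ord])
  }

  primaries <- n
  keep_t <- numeric(); keep_s <- integer()
  for (j in seq_along(tf)) {
    s <- sz[j]
    tries <- 0L
    while (s > primaries - 1 && tries < 50L) {
      if (!is.null(forced_events))
        stop_input("forced clade size exceeds available primary lineages")
      s <- draw_size(1)
      tries <- tries + 1L
    }
    if (tries > 0)
      log_lines <- c(log_lines, sprintf("event at %.3g y: clade size resampled %d time(s)", tf[j], tries))
    if (s > primaries - 1 || primaries < 3) {
      log_lines <- c(log_lines, sprintf("event at %.3g y dropped: no primary lineages left", tf[j]))
      next
    }
    keep_t <- c(keep_t, tf[j]); keep_s <- c(keep_s, s)
    primaries <- primaries - s
  }
  nev <- length(keep_t)
  L <- primaries + nev

  tsplit <- if (L > 1) ew * (seq_len(L - 1) - 1) / max(1, L - 1) else 0
  ev_pos <- if (nev) sort(sample.int(L, nev)) else integer()
  ev_of_pos <- integer(L); ev_of_pos[ev_pos] <- seq_len(nev)

  # branch bookkeeping: each branch spans [t0, t1] and subtends a contiguous
  # range of final tip indices
  bt0 <- numeric(); bt1 <- numeric(); bfrom <- integer(); bto <- integer()
  bkind <- character()
  labs <- character(L)
  tip_cursor <- 0L
  tip_start <- integer(L)
  ev_rows <- data.frame(time = numeric(), size = integer(),
                        tip_from = integer(), tip_to = integer())
  fmt <- function(x) sprintf("%.12g", x)
  for (i in seq_len(L)) {
    a_i <- tsplit[min(i, max(1, L - 1))]
    tip_start[i] <- tip_cursor + 1L
    j <- ev_of_pos[i]
    if (j == 0L) {
      k <- tip_cursor + 1L
      bt0 <- c(bt0, a_i); bt1 <- c(bt1, age)
      bfrom <- c(bfrom, k); bto <- c(bto, k); bkind <- c(bkind, "primary_tip")
      labs[i] <- paste0("t", k, ":", fmt(age - a_i))
      tip_cursor <- k
    } else {
      s <- keep_s[j]; tfj <- keep_t[j]
      first <- tip_cursor + 1L; last <- tip_cursor + s
      bt0 <- c(bt0, a_i); bt1 <- c(bt1, tfj)
      bfrom <- c(bfrom, first); bto <- c(bto, last); bkind <- c(bkind, "ch_founding")
      w <- max(min(params$expansion_window, (age - tfj) / 2), 1e-9)
      ts <- tfj + w * (seq_len(s - 1) - 1) / max(1, s - 1)
      # sub-caterpillar terminal branches
      attach_k <- ts[pmin(seq_len(s), s - 1)]
      bt0 <- c(bt0, attach_k); bt1 <- c(bt1, rep(age, s))
      bfrom <- c(bfrom, first:last); bto <- c(bto, first:last)
      bkind <- c(bkind, rep("ch_tip", s))
      if (s > 2) {
        idx <- seq_len(s - 2)
        bt0 <- c(bt0, ts[idx]); bt1 <- c(bt1, ts[idx + 1])
        bfrom <- c(bfrom, first + idx); bto <- c(bto, rep(last, s - 2))
        bkind <- c(bkind, rep("ch_internal", s - 2))
      }
      sublab <- function(k) paste0("t", first + k - 1L, ":", fmt(age - attach_k[k]))
      str <- paste0("(", sublab(s - 1), ",", sublab(s), ")")
      if (s > 2) for (k in (s - 2):1)
        str <- paste0("(", sublab(k), ",", str, ":", fmt(ts[k + 1] - ts[k]), ")")
      labs[i] <- paste0(str, ":", fmt(tfj - a_i))
      ev_rows <- rbind(ev_rows, data.frame(time = tfj, size = s,
                                           tip_from = first, tip_to = last))
      tip_cursor <- last
    }
  }
  # embryonic internal branches of the main caterpillar
  if (L > 2) {
    idx <- seq_len(L - 2)
    bt0 <- c(bt0, tsplit[idx]); bt1 <- c(bt1, tsplit[idx + 1])
    bfrom <- c(bfrom, tip_start[idx + 1]); bto <- c(bto, rep(n, L - 2))
    bkind <- c(bkind, rep("embryonic", L - 2))
  }
  if (L < 2) stop_input("degenerate simulation: fewer than 2 stem lineages")
  nwk <- paste0("(", labs[L - 1], ",", labs[L], ")")
  if (L > 2) for (i in (L - 2):1)
    nwk <- paste0("(", labs[i], ",", nwk, ":", fmt(tsplit[i + 1] - tsplit[i]), ")")
  nwk <- paste0(nwk, ";")

  branches <- data.frame(branch_id = seq_along(bt0), kind = bkind,
                         t0 = bt0, t1 = bt1, length = bt1 - bt0,
                         tip_from = bfrom, tip_to = bto,
                         tip_count = bto - bfrom + 1L,
                         is_tip = bkind %in% c("primary_tip", "ch_tip"),
                         stringsAsFactors = FALSE)
  branches$n_mutations <- rpois(nrow(branches), params$mutation_rate * branches$length)
  # the somatic clock starts after embryonic diversification: the caterpillar
  # of near-zero embryonic branches is a topology placeholder and carries no
  # mutations, so CH-free individuals have purely tip-private spectra
  branches$n_mutations[branches$kind == "embryonic"] <- 0L

  idx <- which(branches$n_mutations > 0)
  reps <- branches$n_mutations[idx]
  bid <- rep(idx, reps)
  ids <- paste0("v", bid, ".", sequence(reps))
  tc <- branches$tip_count[bid]
  rec <- data.frame(variant_id = ids,
                    mutant_count = tc,
                    nonmutant_count = n - tc,
                    source = "colony_cells", stringsAsFactors = FALSE)
  spectrum <- vfs(rec, sample_id = sample_id, age = age)

  mat <- NULL
  if (genotype) {
    lens <- tc
    ii <- sequence(nvec = lens, from = branches$tip_from[bid])
    jj <- rep(seq_along(bid), lens)
    mat <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                                dims = c(n, length(ids)),
                                dimnames = list(paste0("t", seq_len(n)), ids))
  }

  tree <- structure(list(phylo = ape::read.tree(text = nwk),
                         branches = branches, n_lineages = n),
                    class = "hsc_tree")
  structure(list(age = age, tree = tree, matrix = mat, vfs = spectrum,
                 true_decay = true_decay(tree, params$vaf_threshold),
                 ch_events = ev_rows, seed = seed, params = params,
                 log = log_lines),
            class = "sim_individual")
}

#' @method print sim_individual
#' @export
print.sim_individual <- function(x, ...) {
  cat(sprintf("simulated individual: age %.4g y, %d lineages, %d CH event(s), %d variant(s), true decay %.4g\n",
              x$age, x$tree$n_lineages, nrow(x$ch_events),
              nrow(x$vfs$records), x$true_decay))
  invisible(x)
}

#' Ground-truth diversity decay of a simulated phylogeny
#'
#' Sums, over every non-tip branch whose carrier cell fraction f =
#' tip_count / n_lineages is at least `2 * threshold` (the cell-fraction
#' equivalent of the VAF threshold), the product of the branch's VAF (f/2)
#' and its mutation count.  On noise-free spectra this equals
#' [lambda_metric()] at the same threshold by construction.
#'
#' @param tree an `"hsc_tree"` from [simulate_individual()].
#' @param threshold tip-variant VAF threshold (default 0.01).
#' @return Non-negative scalar decay.
#' @export
true_decay <- function(tree, threshold = 0.01) {
  stopifnot(inherits(tree, "hsc_tree"))
  b <- tree$branches
  n <- tree$n_lineages
  f <- b$tip_count / n
  keep <- !b$is_tip & f >= 2 * threshold
  sum(0.5 * f[keep] * b$n_mutations[keep])
}

#' Simulate a cohort of individuals
#'
#' Each individual is generated from its own substream of the root seed, so
#' cohorts are reproducible and individual i does not depend on how many
#' individuals precede it.
#'
#' @param ages vector of ages in years (one individual each).
#' @param params a [sim_params()] object.
#' @param seed root seed.
#' @param genotype build genotype matrices (default `FALSE`; they are large
#'   for old individuals and most cohort-level analyses only need the VFS).
#' @return List of `"sim_individual"` objects named `sim1`, `sim2`, ...
#' @export
simulate_cohort <- function(ages, params = sim_params(), seed = 1L,
                            genotype = FALSE) {
  if (!length(ages)) stop_input("ages must be non-empty")
  seeds <- substream_seed(seed, paste0("individual", seq_along(ages)))
  out <- lapply(seq_along(ages), function(i)
    simulate_individual(ages[i], params, seed = seeds[i], genotype = genotype,
                        sample_id = paste0("sim", i)))
  names(out) <- paste0("sim", seq_along(ages))
  out
}

#' Generate (age, lambda) pairs directly from the exponential age model
#'
#' Bypasses tree simulation: lambda_i = exp(a + b * age_i + e_i) with
#' e_i ~ N(0, noise_sigma^2).  Intended for fast, exactly-calibrated tests
#' and demonstrations of the age-model machinery.
#'
#' @param a,b model constants; `b` must be positive.
#' @param ages vector of ages in years.
#' @param noise_sigma log-scale noise SD (0 gives a noiseless cohort).
#' @param seed seed for the noise draws.
#' @return data.frame with columns `sample_id`, `age`, `lambda`.
#' @export
calibrated_cohort <- function(a, b, ages, noise_sigma = 0, seed = 1L) {
  if (!is.numeric(b) || b <= 0) stop_input("b must be positive")
  if (!length(ages)) stop_input("ages must be non-empty")
  eps <- if (noise_sigma > 0)
    with_seed(seed, rnorm(length(ages), 0, noise_sigma)) else 0
  data.frame(sample_id = paste0("cal", seq_along(ages)),
             age = ages,
             lambda = exp(a + b * ages + eps))
}

#' Write a simulated cohort to a directory
#'
#' Emits, per individual, the newick tree, the unfiltered VFS TSV, the
#' genotype matrix TSV (when present) and a ground-truth JSON, plus a
#' cohort-level `manifest.tsv`.
#'
#' @param cohort list of `"sim_individual"` objects.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_sim_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(names(cohort), function(nm) {
    ind <- cohort[[nm]]
    ape::write.tree(ind$tree$phylo, file.path(dir, paste0(nm, ".nwk")))
    write_vfs(ind$vfs, file.path(dir, paste0(nm, ".vfs.tsv")))
    if (!is.null(ind$matrix))
      write_genotype_matrix(as.matrix(ind$matrix), file.path(dir, paste0(nm, ".genotypes.tsv")))
    jsonlite::write_json(list(sample_id = nm, age = ind$age, seed = ind$seed,
                              true_decay = ind$true_decay,
                              ch_events = ind$ch_events),
                         file.path(dir, paste0(nm, ".truth.json")),
                         auto_unbox = TRUE, digits = NA)
    data.frame(sample_id = nm, age = ind$age, seed = ind$seed,
               n_variants = nrow(ind$vfs$records), true_decay = ind$true_decay,
               n_ch_events = nrow(ind$ch_events))
  })
  manifest <- file.path(dir, "manifest.tsv")
  write.table(do.call(rbind, rows), manifest, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(manifest)
}
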
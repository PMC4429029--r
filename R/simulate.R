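#' Simulation configuration
#'
#' Describes the synthetic paired tumor/normal three-platform world the
#' generator emulates: a cohort of tumor/normal pairs, a gene panel where
#' each gene carries one expression transcript, a block of methylation
#' probes and a block of SNP/CN probes, and planted gene classes —
#' `null` (no change), `expr_only` (expression change with no epigenetic
#' or copy-number cause), `meth_driven` (methylation shift with inversely
#' coupled expression), `cn_driven` (segmental log-R-ratio shift with
#' positively coupled expression), and `dual` (both causes, acting
#' concordantly on expression).
#'
#' @param n_pairs number of tumor/normal pairs (>= 2).
#' @param n_genes number of genes.
#' @param class_fractions named numeric vector over
#'   `null, expr_only, meth_driven, cn_driven, dual`, summing to 1.
#' @param probes_per_gene_meth,probes_per_gene_cnv integer ranges
#'   `c(min, max)` for per-gene probe counts.
#' @param delta_meth tumor methylation shift for driven genes
#'   (score units).
#' @param delta_lrr tumor log R ratio shift for driven genes.
#' @param beta_meth expression change per unit methylation shift
#'   (log2 units, <= 0: hypermethylation represses).
#' @param gamma_cn expression change per unit LRR shift
#'   (log2 units, >= 0: dosage effect).
#' @param delta_expr_only expression shift for `expr_only` genes (log2).
#' @param sigma_expr,sigma_meth,sigma_lrr per-platform measurement noise
#'   standard deviations.
#' @param rho_pair within-pair baseline correlation in `[0, 1)`; realized
#'   by a latent per-pair baseline shared between the tumor and normal
#'   measurement of each feature.
#' @param frac_probes_affected fraction of a driven gene's probes carrying
#'   the planted shift, as one contiguous run (in `(0, 1]`).
#' @param seed integer seed; the full output is a pure function of the
#'   configuration including the seed.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_pairs = 30L, n_genes = 1000L,
                              class_fractions = c(null = 0.50,
                                                  expr_only = 0.30,
                                                  meth_driven = 0.08,
                                                  cn_driven = 0.10,
                                                  dual = 0.02),
                              probes_per_gene_meth = c(5L, 50L),
                              probes_per_gene_cnv = c(5L, 40L),
                              delta_meth = 0.8, delta_lrr = 0.5,
                              beta_meth = -1.0, gamma_cn = 1.5,
                              delta_expr_only = 1.0,
                              sigma_expr = 0.5, sigma_meth = 0.3,
                              sigma_lrr = 0.2, rho_pair = 0.5,
                              frac_probes_affected = 1.0,
                              seed = 1L) {
  classes <- c("null", "expr_only", "meth_driven", "cn_driven", "dual")
  if (!all(classes %in% names(class_fractions))) {
    stop("class_fractions must name all of: ",
         paste(classes, collapse = ", "))
  }
  class_fractions <- class_fractions[classes]
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    stop("class_fractions must sum to 1")
  }
  if (any(class_fractions < 0)) stop("class_fractions must be non-negative")
  if (n_pairs < 2) stop("n_pairs must be at least 2")
  stopifnot(
    n_genes >= 1,
    length(probes_per_gene_meth) == 2,
    probes_per_gene_meth[1] >= 1,
    probes_per_gene_meth[2] >= probes_per_gene_meth[1],
    length(probes_per_gene_cnv) == 2,
    probes_per_gene_cnv[1] >= 1,
    probes_per_gene_cnv[2] >= probes_per_gene_cnv[1],
    beta_meth <= 0, gamma_cn >= 0,
    sigma_expr > 0, sigma_meth > 0, sigma_lrr > 0,
    rho_pair >= 0, rho_pair < 1,
    frac_probes_affected > 0, frac_probes_affected <= 1
  )
  structure(
    list(n_pairs = as.integer(n_pairs), n_genes = as.integer(n_genes),
         class_fractions = class_fractions,
         probes_per_gene_meth = as.integer(probes_per_gene_meth),
         probes_per_gene_cnv = as.integer(probes_per_gene_cnv),
         delta_meth = delta_meth, delta_lrr = delta_lrr,
         beta_meth = beta_meth, gamma_cn = gamma_cn,
         delta_expr_only = delta_expr_only,
         sigma_expr = sigma_expr, sigma_meth = sigma_meth,
         sigma_lrr = sigma_lrr, rho_pair = rho_pair,
         frac_probes_affected = frac_probes_affected,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# deterministic class counts: floor shares, remainder to the largest
# fractional parts (ties broken by class order)
class_counts <- function(fractions, n_genes) {
  raw <- fractions * n_genes
  counts <- floor(raw)
  rem <- n_genes - sum(counts)
  if (rem > 0) {
    frac <- raw - counts
    extra <- order(-frac, seq_along(frac))[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

# run generator code under an isolated RNG so callers' streams are
# untouched and the output is a pure function of the supplied seed
with_local_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic paired tumor/normal three-platform dataset
#'
#' Builds log2 expression (1 transcript per gene), methylation score and
#' log R ratio matrices for `n_pairs` tumor/normal pairs, a probe
#' annotation laying each gene's probes out consecutively on synthetic
#' chromosomes (so adjacency is well defined), and a truth table recording
#' the planted class and per-platform directions of every gene.
#'
#' For every feature of gene *g* and pair *j*, a latent baseline
#' `b = mu_feature + N(0, sigma * sqrt(rho/(1-rho)))` is shared between
#' the two halves, giving within-pair correlation `rho_pair`; the normal
#' value is `b + N(0, sigma)` and the tumor value adds the planted class
#' shift. Methylation-driven genes shift a contiguous run covering
#' `frac_probes_affected` of their methylation probes by `±delta_meth`
#' (sign drawn once per gene) and shift expression by
#' `beta_meth × (signed shift)`; copy-number-driven genes shift a
#' contiguous run of CN probes by `±delta_lrr` and expression by
#' `gamma_cn × (signed shift)`; `dual` genes carry both shifts with signs
#' chosen concordantly (hypermethylation together with copy loss, or the
#' mirror image, so the two couplings reinforce); `expr_only` genes shift
#' expression by `±delta_expr_only`. Identical configurations (including
#' the seed) produce bit-identical output, and every gene draws from its
#' own seeded substream so enlarging the panel does not perturb earlier
#' genes.
#'
#' @param config a [simulation_config()].
#' @return a list with elements `expression`, `methylation`, `cnv`
#'   (each a [paired_omics_matrix()]), `annotation`
#'   (a [probe_annotation()]), and `truth` (a `data.frame` with
#'   `gene_symbol`, `gene_class`, `planted_expr_direction`,
#'   `planted_meth_direction`, `planted_cn_direction`).
#' @export
generate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  classes <- c("null", "expr_only", "meth_driven", "cn_driven", "dual")
  counts <- class_counts(config$class_fractions, config$n_genes)
  gene_class <- rep(classes, counts)
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  pair_ids <- sprintf("p%02d", seq_len(config$n_pairs))
  np <- config$n_pairs

  dir_of <- function(shift) {
    if (shift > 0) "up" else if (shift < 0) "down" else "none"
  }
  sim_block <- function(mu, shift, sigma, rho) {
    # mu, shift: per-feature; returns list(tumor, normal) feature x pair
    nf <- length(mu)
    sigma_b <- sigma * sqrt(rho / (1 - rho))
    b <- mu + matrix(rnorm(nf * np, 0, sigma_b), nf, np)
    normal <- b + matrix(rnorm(nf * np, 0, sigma), nf, np)
    tumor <- b + shift + matrix(rnorm(nf * np, 0, sigma), nf, np)
    list(tumor = tumor, normal = normal)
  }

  res <- with_local_rng(config$seed, {
    expr_t <- expr_n <- vector("list", config$n_genes)
    meth_t <- meth_n <- vector("list", config$n_genes)
    cnv_t <- cnv_n <- vector("list", config$n_genes)
    ann_rows <- vector("list", config$n_genes)
    truth <- data.frame(
      gene_symbol = genes, gene_class = gene_class,
      planted_expr_direction = "none", planted_meth_direction = "none",
      planted_cn_direction = "none", stringsAsFactors = FALSE
    )
    for (i in seq_len(config$n_genes)) {
      # per-gene substream: stable under changes of n_genes
      set.seed((config$seed + i * 1000003) %% 2147483647)
      g <- genes[i]
      cls <- gene_class[i]
      n_m <- sample(seq(config$probes_per_gene_meth[1],
                        config$probes_per_gene_meth[2]), 1)
      n_c <- sample(seq(config$probes_per_gene_cnv[1],
                        config$probes_per_gene_cnv[2]), 1)

      meth_sign <- 0; cn_sign <- 0; expr_shift <- 0
      if (cls == "expr_only") {
        expr_shift <- sample(c(-1, 1), 1) * config$delta_expr_only
      } else if (cls == "meth_driven") {
        meth_sign <- sample(c(-1, 1), 1)
        expr_shift <- config$beta_meth * meth_sign * config$delta_meth
      } else if (cls == "cn_driven") {
        cn_sign <- sample(c(-1, 1), 1)
        expr_shift <- config$gamma_cn * cn_sign * config$delta_lrr
      } else if (cls == "dual") {
        s <- sample(c(-1, 1), 1)
        meth_sign <- -s   # hypermethylation represses: meth opposes expr
        cn_sign <- s      # dosage: copy number moves with expr
        expr_shift <- config$beta_meth * meth_sign * config$delta_meth +
          config$gamma_cn * cn_sign * config$delta_lrr
      }

      meth_shift <- rep(0, n_m)
      if (meth_sign != 0) {
        k <- max(1L, as.integer(round(config$frac_probes_affected * n_m)))
        start <- if (k < n_m) sample(n_m - k + 1L, 1) else 1L
        meth_shift[start:(start + k - 1L)] <-
          meth_sign * config$delta_meth
      }
      cnv_shift <- rep(0, n_c)
      if (cn_sign != 0) {
        k <- max(1L, as.integer(round(config$frac_probes_affected * n_c)))
        start <- if (k < n_c) sample(n_c - k + 1L, 1) else 1L
        cnv_shift[start:(start + k - 1L)] <- cn_sign * config$delta_lrr
      }

      truth$planted_expr_direction[i] <- dir_of(expr_shift)
      truth$planted_meth_direction[i] <- dir_of(meth_sign)
      truth$planted_cn_direction[i] <- dir_of(cn_sign)

      mu_e <- rnorm(1, 8, 1)
      mu_m <- rnorm(n_m, 0, 1)
      mu_c <- rep(0, n_c)
      eb <- sim_block(mu_e, expr_shift, config$sigma_expr, config$rho_pair)
      mb <- sim_block(mu_m, meth_shift, config$sigma_meth, config$rho_pair)
      cb <- sim_block(mu_c, cnv_shift, config$sigma_lrr, config$rho_pair)

      tx_id <- paste0(g, "_tx1")
      m_ids <- sprintf("%s_m%02d", g, seq_len(n_m))
      c_ids <- sprintf("%s_c%02d", g, seq_len(n_c))
      rownames(eb$tumor) <- rownames(eb$normal) <- tx_id
      rownames(mb$tumor) <- rownames(mb$normal) <- m_ids
      rownames(cb$tumor) <- rownames(cb$normal) <- c_ids
      expr_t[[i]] <- eb$tumor; expr_n[[i]] <- eb$normal
      meth_t[[i]] <- mb$tumor; meth_n[[i]] <- mb$normal
      cnv_t[[i]] <- cb$tumor; cnv_n[[i]] <- cb$normal

      # consecutive layout: each gene owns a 1 Mb window on a chromosome
      chrom <- paste0("chr", ((i - 1L) %% 22L) + 1L)
      base <- (((i - 1L) %/% 22L) + 1L) * 1000000L
      ann_rows[[i]] <- data.frame(
        chromosome = chrom,
        start = c(base, base + 2000L + (seq_len(n_m) - 1L) * 100L,
                  base + 200000L + (seq_len(n_c) - 1L) * 100L),
        end = c(base + 1000L, base + 2000L + (seq_len(n_m) - 1L) * 100L + 50L,
                base + 200000L + (seq_len(n_c) - 1L) * 100L + 1L),
        probe_id = c(tx_id, m_ids, c_ids),
        score = 0, strand = ".",
        platform = c("expression", rep("methylation", n_m),
                     rep("cnv", n_c)),
        gene_symbol = g, stringsAsFactors = FALSE
      )
    }
    bindm <- function(lst) {
      m <- do.call(rbind, lst)
      colnames(m) <- pair_ids
      m
    }
    ann <- do.call(rbind, ann_rows)
    list(
      expression = paired_omics_matrix(bindm(expr_t), bindm(expr_n),
                                       "expression"),
      methylation = paired_omics_matrix(bindm(meth_t), bindm(meth_n),
                                        "methylation"),
      cnv = paired_omics_matrix(bindm(cnv_t), bindm(cnv_n), "cnv"),
      annotation = probe_annotation(
        chromosome = ann$chromosome, start = ann$start, end = ann$end,
        probe_id = ann$probe_id, score = ann$score, strand = ann$strand,
        platform = ann$platform, gene_symbol = ann$gene_symbol
      ),
      truth = truth
    )
  })
  res
}

#' Truth-table explained fractions
#'
#' Independent oracle for the contribution report: among genes with a
#' planted expression change, the fraction whose class is methylation
#' driven (`meth_driven` or `dual`), copy-number driven (`cn_driven` or
#' `dual`), or driven by either (`union`: any class other than
#' `expr_only`).
#'
#' @param truth the `truth` component of [generate_dataset()] output.
#' @return a list `meth`, `cn`, `union`, `n_expr_changed`, and
#'   `zero_denominator` (`TRUE`, with zero fractions, when no gene has a
#'   planted expression change).
#' @export
truth_explained_fractions <- function(truth) {
  stopifnot(nrow(truth) > 0)
  changed <- truth[truth$planted_expr_direction != "none", , drop = FALSE]
  n <- nrow(changed)
  if (n == 0) {
    return(list(meth = 0, cn = 0, union = 0, n_expr_changed = 0L,
                zero_denominator = TRUE))
  }
  list(
    meth = sum(changed$gene_class %in% c("meth_driven", "dual")) / n,
    cn = sum(changed$gene_class %in% c("cn_driven", "dual")) / n,
    union = sum(changed$gene_class %in%
                  c("meth_driven", "cn_driven", "dual")) / n,
    n_expr_changed = n, zero_denominator = FALSE
  )
}

#' Write a simulated dataset to a directory
#'
#' Writes `expression.tsv`, `methylation.tsv`, `cnv.tsv` (matrix TSV
#' format of [write_matrix()]), `probes.bed` ([write_annotation()]) and
#' `truth.tsv`.
#'
#' @param dataset [generate_dataset()] output.
#' @param dir output directory, created if absent.
#' @return invisibly, `dir`.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_matrix(dataset$expression, file.path(dir, "expression.tsv"))
  write_matrix(dataset$methylation, file.path(dir, "methylation.tsv"))
  write_matrix(dataset$cnv, file.path(dir, "cnv.tsv"))
  write_annotation(dataset$annotation, file.path(dir, "probes.bed"))
  write.table(dataset$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
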
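#' Default experiment configuration
#'
#' @param ... Overrides of the defaults.
#' @return A config list for \code{run_experiment}.
#' @export
experiment_config <- function(...) {
  cfg <- list(
    trees = NULL,            # path to a tree file, or a multiPhylo
    counts = NULL,           # path to a counts file, or a named vector
    simulate_seed = NULL,    # or: build the study-like fixture from this seed
    sim_n_trees = 25L,
    methods = c("MP", "ML-CE", "ML-ordered", "BI-fixed", "BI-RJ"),
    families = c("CRND", "CRDD"),    # ML-CE candidate set
    rescale = 5,
    cutoff = 1e-2,
    consensus = 0.95,
    max_trees = 25L,         # trees analyzed per likelihood-based method
    max_trees_bayes = 4L,    # trees analyzed per MCMC method
    n_maps = 250L,
    iterations = 4000L, burnin = 400L, thin = 10L,
    seed = 1L,
    out_dir = NULL
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

read_experiment_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the yaml package")
  }
  do.call(experiment_config, yaml::yaml.load_file(path))
}

# uniform probability matrix over MPR sets, clade-keyed like
# marginal_reconstruction, so parsimony feeds the same integration code
mpr_probabilities <- function(recon) {
  tree <- recon$tree
  ntip <- ape::Ntip(tree)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  states <- recon$states
  m <- matrix(0, length(internal), length(states),
              dimnames = list(clade_keys(tree)[internal], states))
  for (i in seq_along(internal)) {
    s <- recon$mpr[[internal[i]]]
    m[i, match(s, states)] <- 1 / length(s)
  }
  m
}

# align reconstruction matrices onto a common state set (union of columns)
align_states <- function(recons) {
  states <- sort(unique(as.integer(unlist(lapply(recons, colnames)))))
  lapply(recons, function(r) {
    out <- matrix(0, nrow(r), length(states),
                  dimnames = list(rownames(r), states))
    out[, colnames(r)] <- r
    out
  })
}

method_stage <- function(method, trees, counts, space, cfg) {
  n_use <- length(trees)
  recons <- vector("list", n_use)
  gl <- rep(NA_real_, n_use)
  seed <- cfg$seed
  if (method == "MP") {
    for (i in seq_len(n_use)) {
      rec <- sankoff_ordered(trees[[i]], counts)
      recons[[i]] <- mpr_probabilities(rec)
      gl[i] <- mp_gl(trees[[i]], rec, counts)$gl
    }
  } else if (method == "ML-CE") {
    for (i in seq_len(n_use)) {
      fits <- fit_chromevol_family(trees[[i]], counts, space,
                                   families = cfg$families,
                                   restarts = 2L, seed = seed + i)
      tab <- aic_table(fits)
      w <- stats::setNames(tab$akaike_weight, tab$model)[names(fits)]
      per_model <- lapply(fits, function(f)
        marginal_reconstruction(trees[[i]], counts, f$model))
      recons[[i]] <- model_average(per_model, unname(w))
      ev <- vapply(fits, function(f)
        expected_events(trees[[i]], counts, f$model,
                        n_maps = cfg$n_maps, seed = seed + i)$gl, 0)
      gl[i] <- sum(unname(w) * ev)
    }
  } else if (method == "ML-ordered") {
    lspace <- chrom_state_space(space$observed, n_min = min(space$observed),
                                n_max = max(space$observed))
    lspace$observed <- space$observed
    spec <- chrom_model_spec("ORDERED_K", "two", lspace)
    for (i in seq_len(n_use)) {
      fit <- fit_ml(trees[[i]], counts, spec, lspace,
                    restarts = 2L, seed = seed + i)
      recons[[i]] <- marginal_reconstruction(trees[[i]], counts, fit$model)
      gl[i] <- gl_telescoping(trees[[i]], counts, fit$model)$gl
    }
  } else if (method == "BI-fixed") {
    lspace <- ladder_space(space)
    spec <- chrom_model_spec("ORDERED_K", "two", lspace)
    for (i in seq_len(n_use)) {
      ch <- suppressWarnings(mcmc_fixed(trees[[i]], counts, spec,
                 iterations = cfg$iterations, burnin = cfg$burnin,
                 thin = cfg$thin, seed = seed + i, space = lspace))
      post_mean <- colMeans(ch$samples[, c("rate_up", "rate_down"), drop = FALSE])
      model <- build_q(spec, post_mean, lspace)
      recons[[i]] <- marginal_reconstruction(trees[[i]], counts, model)
      gl[i] <- gl_telescoping(trees[[i]], counts, model)$gl
    }
  } else if (method == "BI-RJ") {
    lspace <- ladder_space(space)
    for (i in seq_len(n_use)) {
      rj <- suppressWarnings(rj_mcmc(trees[[i]], counts,
                 iterations = cfg$iterations, burnin = cfg$burnin,
                 thin = cfg$thin, seed = seed + i, space = lspace))
      take <- unique(round(seq(1L, length(rj$z), length.out = min(25L, length(rj$z)))))
      acc <- NULL; gsum <- 0
      for (s in take) {
        spec_s <- chrom_model_spec("FULL_MK", rate_classes = rj$z[[s]],
                                   space = lspace)
        model_s <- suppressWarnings(build_q(spec_s, rj$theta[[s]], lspace))
        r_s <- tryCatch(marginal_reconstruction(trees[[i]], counts, model_s),
                        error = function(e) NULL)
        if (is.null(r_s)) next
        acc <- if (is.null(acc)) r_s else acc + r_s
        gsum <- gsum + gl_telescoping(trees[[i]], counts, model_s)$gl
      }
      if (is.null(acc)) stop("no usable posterior model samples for tree ", i)
      recons[[i]] <- acc / length(take)
      gl[i] <- gsum / length(take)
    }
  } else stop("unknown method: ", method)
  list(recons = align_states(recons), gl = gl)
}

ladder_space <- function(space) {
  ls <- chrom_state_space(space$observed, n_min = min(space$observed),
                          n_max = max(space$observed))
  ls$observed <- space$observed
  ls
}

#' Run the full comparison experiment
#'
#' Orchestrates, for one tree set and count table: branch-length rescaling,
#' consensus and MCC construction, then per method (ordered parsimony,
#' AIC-averaged dysploidy/polyploidy ML, ordered-ladder ML, fixed-model and
#' reversible-jump Bayesian inference): per-tree reconstruction, G-L,
#' integration onto the consensus and MCC clades, precision statistics,
#' precision correlations and the MCC-deviation table. Likelihood-based
#' methods analyze up to \code{max_trees} trees and the MCMC methods up to
#' \code{max_trees_bayes} (posterior sets are subsampled evenly), keeping
#' desk-scale runs tractable; raise the caps for full runs.
#'
#' @param config A list from \code{experiment_config}, or a path to a YAML
#'   file of overrides.
#' @return A report list (also written to \code{config$out_dir} as JSON/TSV/
#'   annotated NEXUS when set): per method G-L summary and precision
#'   statistics, plus the consensus and MCC trees.
#' @export
run_experiment <- function(config = experiment_config()) {
  if (is.character(config)) config <- read_experiment_config(config)
  cfg <- do.call(experiment_config, config)
  stopifnot(length(cfg$methods) >= 1L)

  if (!is.null(cfg$simulate_seed)) {
    fx <- melampodium_like_fixture(cfg$simulate_seed, n_trees = cfg$sim_n_trees)
    trees <- fx$trees; counts <- fx$counts
  } else {
    trees <- if (is.character(cfg$trees)) read_tree_set(cfg$trees) else as_tree_set(cfg$trees)
    counts <- if (is.character(cfg$counts)) read_counts(cfg$counts) else cfg$counts
  }
  trees <- as_tree_set(lapply(trees, rescale_total_length, target = cfg$rescale),
                       provenance = attr(trees, "provenance"))
  counts <- check_counts(counts, trees[[1L]])
  space <- chrom_state_space(counts)

  cons <- majority_consensus(trees, cfg$consensus)
  mcc <- mcc_tree(trees)
  mcc_idx <- attr(mcc, "index")

  report <- list(config = cfg, n_trees = length(trees),
                 consensus = cons, mcc_index = mcc_idx, methods = list())
  failures <- character(0)
  for (method in cfg$methods) {
    res <- tryCatch({
      cap <- if (method %in% c("BI-fixed", "BI-RJ")) cfg$max_trees_bayes else cfg$max_trees
      use <- unique(round(seq(1L, length(trees), length.out = min(cap, length(trees)))))
      if (!(mcc_idx %in% use)) use <- sort(c(use[-length(use)], mcc_idx))
      sub <- as_tree_set(trees[use])
      st <- method_stage(method, sub, counts, space, cfg)
      mcc_pos <- match(mcc_idx, use)

      union <- build_state_union(st$recons, cfg$cutoff)
      integ <- integrate_reconstructions(sub, st$recons, cons)
      integ_prec <- precision_stats(integ$probs, union)
      mcc_recon <- st$recons[[mcc_pos]]
      mcc_on_cons <- mcc_recon[intersect(rownames(integ$probs), rownames(mcc_recon)), ,
                               drop = FALSE]
      mcc_prec <- precision_stats(mcc_recon, union)
      mcc_prec_shared <- precision_stats(mcc_on_cons, union)

      per_tree_rp <- lapply(rownames(integ$probs), function(cl) {
        vals <- vapply(st$recons, function(r) {
          if (cl %in% rownames(r)) {
            rp_node(r[cl, as.character(union$states)], union$c_x)
          } else NA_real_
        }, 0)
        vals[!is.na(vals)]
      })
      names(per_tree_rp) <- rownames(integ$probs)
      corr <- lapply(c(0.90, 0.95), function(th) {
        if (length(per_tree_rp) >= 3L) {
          precision_correlation(integ_prec$rp_n, per_tree_rp, th)
        } else list(r = NA_real_, note = "fewer than 3 clades")
      })
      names(corr) <- c("0.90", "0.95")
      dev_tab <- mcc_deviation_table(integ_prec$rp_n, mcc_prec_shared$rp_n)
      gl <- gl_summary(st$gl, mcc_value = st$gl[mcc_pos])
      list(trees_used = use, gl = gl,
           consensus_precision = integ_prec, mcc_precision = mcc_prec,
           correlation = corr, mcc_deviation = dev_tab,
           integrated = integ, state_union = union)
    }, error = function(e) {
      failures <<- c(failures, paste0(method, ": ", conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) report$methods[[method]] <- res
  }
  report$failures <- failures
  if (!is.null(cfg$out_dir)) write_experiment_report(report, cfg$out_dir)
  report
}

write_experiment_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(
    n_trees = report$n_trees,
    mcc_index = report$mcc_index,
    seed = report$config$seed,
    methods = lapply(report$methods, function(m) list(
      gl = list(mean = m$gl$mean, median = m$gl$median,
                mode = m$gl$mode, range = m$gl$range,
                mcc = m$gl$mcc_value),
      rp_t_consensus = m$consensus_precision$rp_t,
      rp_t_mcc = m$mcc_precision$rp_t,
      rp_n_range = m$consensus_precision$range,
      correlation = lapply(m$correlation, `[[`, "r")
    )),
    failures = report$failures
  )
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (method in names(report$methods)) {
    m <- report$methods[[method]]
    utils::write.table(
      data.frame(tree = m$trees_used, gl = m$gl$values),
      file.path(out_dir, paste0("gl_", gsub("[^A-Za-z]", "_", method), ".tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(
      data.frame(clade = names(m$consensus_precision$rp_n),
                 rp_n = unname(m$consensus_precision$rp_n)),
      file.path(out_dir, paste0("rp_", gsub("[^A-Za-z]", "_", method), ".tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  # consensus tree with integrated probabilities of the first method
  if (length(report$methods)) {
    m1 <- report$methods[[1L]]
    ann <- lapply(seq_len(nrow(m1$integrated$probs)), function(i) {
      v <- m1$integrated$probs[i, ]
      stats::setNames(format(v, digits = 4), paste0("p", colnames(m1$integrated$probs)))
    })
    names(ann) <- rownames(m1$integrated$probs)
    write_annotated_nexus(report$consensus,
                          file.path(out_dir, "consensus_annotated.nex"), ann)
  }
  invisible(out_dir)
}
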
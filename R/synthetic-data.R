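with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(as.integer(seed))
  expr
}

#' Simulate a Yule tree
#'
#' A pure-birth (Yule) ultrametric rooted binary tree with a fixed number of
#' tips, the speciation model used as tree prior throughout.
#'
#' @param n_tips Number of tips (>= 3).
#' @param birth_rate Speciation rate per lineage per unit time.
#' @param seed Integer seed; the tree is reproducible.
#' @return A \code{phylo} with tip labels \code{t1..tN}.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = 1L) {
  stopifnot(n_tips >= 3L, birth_rate > 0)
  with_seed(seed, {
    tr <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
    tr$tip.label <- paste0("t", seq_len(n_tips))
    tr
  })
}

#' Simulate chromosome counts along a tree
#'
#' Gillespie simulation of the chromosome-number CTMC down every branch from
#' a given root state. Every realized event is recorded with its branch,
#' type (dysploid gain/loss, duplication, demi-duplication) and the states
#' it connects, giving a full ground truth for parameter- and event-recovery
#' checks.
#'
#' @param tree Rooted \code{phylo} with branch lengths.
#' @param model A \code{chrom_qmodel}.
#' @param root_state Integer root chromosome number (in the state space).
#' @param seed Integer seed.
#' @return List of class \code{chrom_sim}: \code{counts} (named integer
#'   vector for the tips), \code{node_states} (all nodes, ape indexing on
#'   the returned \code{tree}), \code{events} (data frame: edge, from, to,
#'   type, time), per-type totals, and \code{gl_true} (unit gains minus
#'   losses over the tree).
#' @export
simulate_counts <- function(tree, model, root_state, seed = 1L) {
  states <- model$states
  S <- length(states)
  r0 <- match(as.integer(root_state), states)
  if (is.na(r0)) stop("root_state ", root_state, " not in the state space")
  post <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(post)
  nn <- ntip + post$Nnode
  with_seed(seed, {
    node_states <- integer(nn)
    node_states[ntip + 1L] <- r0
    ev_edge <- integer(0); ev_from <- integer(0); ev_to <- integer(0)
    ev_type <- character(0); ev_time <- numeric(0)
    for (k in rev(seq_len(nrow(post$edge)))) {   # preorder
      par <- post$edge[k, 1L]; chi <- post$edge[k, 2L]
      cur <- node_states[par]
      t_left <- post$edge.length[k]
      elapsed <- 0
      repeat {
        tot <- -model$Q[cur, cur]
        if (tot <= 0) break
        w <- stats::rexp(1L, tot)
        if (w > t_left) break
        t_left <- t_left - w; elapsed <- elapsed + w
        rates <- model$Q[cur, ]; rates[cur] <- 0
        nxt <- sample.int(S, 1L, prob = rates)
        ev <- classify_jump(model, cur, nxt, stats::runif(1L))
        type <- names(ev)[ev != 0][1L]
        ev_edge <- c(ev_edge, k); ev_from <- c(ev_from, states[cur])
        ev_to <- c(ev_to, states[nxt]); ev_type <- c(ev_type, type)
        ev_time <- c(ev_time, elapsed)
        cur <- nxt
      }
      node_states[chi] <- cur
    }
    events <- data.frame(edge = ev_edge, from = ev_from, to = ev_to,
                         type = ev_type, time = ev_time,
                         stringsAsFactors = FALSE)
    gains <- sum(pmax(events$to - events$from, 0)[events$type == "gain"])
    losses <- sum(pmax(events$from - events$to, 0)[events$type == "loss"])
    counts <- stats::setNames(states[node_states[seq_len(ntip)]], post$tip.label)
    structure(list(tree = post, counts = counts,
                   node_states = states[node_states], events = events,
                   gains = gains, losses = losses,
                   duplications = sum(events$type == "dupl"),
                   demi_duplications = sum(events$type == "demi"),
                   gl_true = gains - losses,
                   model = model, root_state = as.integer(root_state),
                   seed = as.integer(seed)),
              class = "chrom_sim")
  })
}

# one rooted NNI move in place: swap a random internal node's child with its
# sibling, keeping each subtree's branch lengths
rooted_nni <- function(tree) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  internals <- setdiff(unique(tree$edge[, 1L]), integer(0))
  cand <- setdiff(tree$edge[tree$edge[, 2L] > ntip, 2L], root)
  if (length(cand) == 0L) return(tree)
  c_node <- if (length(cand) == 1L) cand else sample(cand, 1L)
  p_row <- which(tree$edge[, 2L] == c_node)
  p_node <- tree$edge[p_row, 1L]
  sib_rows <- which(tree$edge[, 1L] == p_node & tree$edge[, 2L] != c_node)
  child_rows <- which(tree$edge[, 1L] == c_node)
  if (length(sib_rows) == 0L || length(child_rows) == 0L) return(tree)
  sr <- if (length(sib_rows) == 1L) sib_rows else sample(sib_rows, 1L)
  cr <- if (length(child_rows) == 1L) child_rows else sample(child_rows, 1L)
  tmp <- tree$edge[sr, 2L]
  tree$edge[sr, 2L] <- tree$edge[cr, 2L]
  tree$edge[cr, 2L] <- tmp
  ape::reorder.phylo(tree, "cladewise")
}

#' Generate a pseudo-posterior tree set
#'
#' Emulates the statistical character of a Bayesian posterior tree sample
#' around a signal tree: each member is a copy of \code{tree} with a
#' Poisson-distributed number of random rooted NNI rearrangements and
#' lognormal branch-length jitter. This is an input generator for testing
#' tree-set machinery, not a substitute for phylogenetic inference.
#'
#' @param tree Rooted \code{phylo} with branch lengths.
#' @param n_trees Number of trees in the set.
#' @param nni_moves Mean number of NNI moves per tree (Poisson).
#' @param bl_jitter_sd Standard deviation of the log-scale branch-length
#'   jitter (0 = none).
#' @param seed Integer seed.
#' @return A \code{multiPhylo} tree set with provenance
#'   \code{"pseudo_posterior"}.
#' @export
pseudo_posterior <- function(tree, n_trees, nni_moves = 1, bl_jitter_sd = 0.1,
                             seed = 1L) {
  stopifnot(n_trees >= 1L, nni_moves >= 0, bl_jitter_sd >= 0)
  with_seed(seed, {
    trees <- vector("list", n_trees)
    for (i in seq_len(n_trees)) {
      tr <- tree
      n_mv <- stats::rpois(1L, nni_moves)
      for (j in seq_len(n_mv)) tr <- rooted_nni(tr)
      if (bl_jitter_sd > 0) {
        tr$edge.length <- tr$edge.length *
          stats::rlnorm(length(tr$edge.length), 0, bl_jitter_sd)
      }
      trees[[i]] <- tr
    }
    as_tree_set(trees, provenance = "pseudo_posterior")
  })
}

#' Desk-scale study-like test bundle
#'
#' A reproducible bundle emulating the structure of the motivating study:
#' a 39-tip Yule tree rescaled to total length 5, haploid counts around a
#' five-state ladder simulated under the constant-rate no-duplication model
#' from root count 11 on states 9..14, and a 450-tree pseudo-posterior
#' sample around the signal tree.
#'
#' @param seed Integer seed.
#' @param n_trees Size of the pseudo-posterior sample (default 450).
#' @param gain,loss Dysploid gain and loss rates per unit branch length.
#' @return List: \code{tree}, \code{counts}, \code{trees} (the tree set),
#'   \code{truth} (the \code{chrom_sim}), \code{space}, \code{model}.
#' @export
melampodium_like_fixture <- function(seed = 1L, n_trees = 450L,
                                     gain = 0.4, loss = 0.4) {
  tree <- simulate_yule_tree(39L, birth_rate = 1, seed = seed)
  tree <- rescale_total_length(tree, 5)
  space <- chrom_state_space(c(9L, 10L, 11L, 12L, 14L), n_min = 9L, n_max = 14L)
  spec <- chrom_model_spec("CRND")
  model <- build_q(spec, c(gain = gain, loss = loss), space)
  sim <- simulate_counts(tree, model, root_state = 11L, seed = seed + 1L)
  trees <- pseudo_posterior(tree, n_trees = n_trees, nni_moves = 1,
                            bl_jitter_sd = 0.1, seed = seed + 2L)
  list(tree = sim$tree, counts = sim$counts, trees = trees, truth = sim,
       space = chrom_state_space(sim$counts), model = model,
       seed = as.integer(seed))
}
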
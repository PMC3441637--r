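# Independent oracles used by the unit and acceptance tests. They share no
# code path with the implementation they check: the dating oracle
# enumerates every gain scenario; the codon oracle enumerates mutational
# pathways recursively.

# ---- trees used across tests -------------------------------------------

tree3 <- function() ape::read.tree(text = "((human,chimp),rhesus);")
tree5 <- function() ape::read.tree(text = "((human,chimp),(rhesus,(mouse,dog)));")
tree6 <- function() ape::read.tree(
  text = "((((human,chimp),orangutan),rhesus),(mouse,dog));")

# ---- brute-force single-gain / zero-loss dating oracle -----------------

# Enumerates every clade of the tree as a candidate gain branch; a
# scenario is consistent when no unambiguous state contradicts it
# (present leaves inside the clade, absent leaves outside). Status:
# contradictory when no scenario is consistent; among consistent
# scenarios parsimony picks the minimal clade (MRCA of present leaves);
# dated only when an unambiguous absent out-group excludes older origins.
oracle_assign_status <- function(tree, states) {
  tips <- tree$tip.label
  clades <- c(as.list(tips),
              lapply(ape::prop.part(tree), function(i) tips[i]))
  present <- names(states)[states == "present"]
  if (length(present) == 0) return(list(status = "undatable", branch = NA))
  consistent <- Filter(function(C) {
    inside <- states[intersect(names(states), C)]
    outside <- states[setdiff(names(states), C)]
    all(present %in% C) && !any(inside == "absent") &&
      !any(outside == "present")
  }, clades)
  if (length(consistent) == 0)
    return(list(status = "contradictory", branch = NA))
  minimal <- consistent[[which.min(lengths(consistent))]]
  outg <- setdiff(tips, minimal)
  out_states <- states[intersect(names(states), outg)]
  if (length(outg) > 0 && !any(out_states == "absent"))
    return(list(status = "undatable", branch = NA))
  list(status = "dated", branch = paste(sort(minimal), collapse = "+"))
}

# all 3^k presence profiles over the tips of a tree
all_profiles <- function(tree) {
  tips <- tree$tip.label
  grid <- expand.grid(rep(list(c("present", "absent", "ambiguous")),
                          length(tips)), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    stats::setNames(unlist(grid[i, ]), tips))
}

# ---- recursive Nei-Gojobori pathway oracle -----------------------------

GC <- Biostrings::GENETIC_CODE
ORACLE_STOPS <- names(GC)[GC == "*"]
ORACLE_SENSE <- setdiff(names(GC), ORACLE_STOPS)

# synonymous sites of a codon: per position, the fraction of non-nonsense
# single-base changes that preserve the amino acid
oracle_syn_sites <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    muts <- vapply(setdiff(c("A", "C", "G", "T"),
                           substr(codon, pos, pos)), function(b) {
      mut <- codon; substr(mut, pos, pos) <- b; mut
    }, character(1))
    ok <- muts[!(muts %in% ORACLE_STOPS)]
    if (length(ok))
      s <- s + mean(vapply(ok, function(m) GC[[m]] == GC[[codon]],
                           logical(1)))
  }
  s
}

# enumerate all mutational pathways recursively; returns a matrix with one
# row (sd, nd, has_stop) per complete pathway
oracle_paths <- function(from, to) {
  diff_pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
  if (length(diff_pos) == 0) return(matrix(c(0, 0, 0), 1))
  out <- NULL
  for (p in diff_pos) {
    nxt <- from
    substr(nxt, p, p) <- substr(to, p, p)
    syn <- !(from %in% ORACLE_STOPS) && !(nxt %in% ORACLE_STOPS) &&
      GC[[from]] == GC[[nxt]]
    sub <- oracle_paths(nxt, to)
    sub[, 1] <- sub[, 1] + as.numeric(syn)
    sub[, 2] <- sub[, 2] + as.numeric(!syn)
    sub[, 3] <- sub[, 3] | (nxt %in% ORACLE_STOPS && nxt != to)
    out <- rbind(out, sub)
  }
  out
}

oracle_pair_diffs <- function(from, to) {
  m <- oracle_paths(from, to)
  keep <- m[m[, 3] == 0, , drop = FALSE]
  if (nrow(keep) == 0) keep <- m
  c(sd = mean(keep[, 1]), nd = mean(keep[, 2]))
}
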
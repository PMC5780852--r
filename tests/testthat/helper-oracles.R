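# Independent brute-force oracles and small fixture builders used across
# the suite. Each oracle is coded directly from the operation's definition,
# with a different algorithm than the package implementation.

# markers = profiles with count exactly 1 in every genome (column scan)
bf_select_markers <- function(m) {
  out <- character(0)
  for (p in colnames(m)) {
    ok <- TRUE
    for (g in rownames(m)) {
      if (m[g, p] != 1) {
        ok <- FALSE
        break
      }
    }
    if (ok) out <- c(out, p)
  }
  sort(out)
}

random_copy_matrix <- function(n_genomes, n_profiles) {
  m <- matrix(sample(0:3, n_genomes * n_profiles, replace = TRUE,
                     prob = c(0.35, 0.45, 0.15, 0.05)),
              nrow = n_genomes,
              dimnames = list(sprintf("G%02d", seq_len(n_genomes)),
                              sprintf("PF%05d", seq_len(n_profiles))))
  # package invariant: every profile column has a nonzero entry
  empty <- colSums(m) == 0
  m[1, empty] <- 1L
  m
}

# conserved-block selection, per-column scans (steps 1-4 verbatim)
bf_select_blocks <- function(classes, config = markertree::trim_config()) {
  n <- length(classes)
  rej <- classes == "gap"
  for (i in seq_len(n)) {
    if (classes[i] == "gap") {
      j <- i - 1
      while (j >= 1 && classes[j] == "nonconserved") {
        rej[j] <- TRUE
        j <- j - 1
      }
      j <- i + 1
      while (j <= n && classes[j] == "nonconserved") {
        rej[j] <- TRUE
        j <- j + 1
      }
    }
  }
  i <- 1
  while (i <= n) {
    if (!rej[i] && classes[i] == "nonconserved") {
      j <- i
      while (j <= n && !rej[j] && classes[j] == "nonconserved") j <- j + 1
      if (j - i > config$max_nonconserved_run) rej[i:(j - 1)] <- TRUE
      i <- j
    } else {
      i <- i + 1
    }
  }
  keep <- integer(0)
  i <- 1
  while (i <= n) {
    if (!rej[i]) {
      j <- i
      while (j <= n && !rej[j]) j <- j + 1
      seg <- i:(j - 1)
      while (length(seg) > 0 && classes[seg[1]] != "highly_conserved") {
        seg <- seg[-1]
      }
      while (length(seg) > 0 && classes[seg[length(seg)]] != "highly_conserved") {
        seg <- seg[-length(seg)]
      }
      if (length(seg) >= config$min_block_len) keep <- c(keep, seg)
      i <- j
    } else {
      i <- i + 1
    }
  }
  keep
}

random_class_string <- function(len) {
  sample(c("gap", "nonconserved", "conserved", "highly_conserved"),
         len, replace = TRUE, prob = c(0.15, 0.3, 0.25, 0.3))
}

# optimal global affine-gap score by exhaustive enumeration of alignment
# paths (gap run of length k costs open + k * ext); tiny inputs only
enum_pairwise_score <- function(a, b, open = -11, ext = -1) {
  S <- markertree:::scoring_matrix("BLOSUM62")
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  la <- length(ca)
  lb <- length(cb)
  rec <- function(i, j, last) {
    if (i > la && j > lb) return(0)
    best <- -Inf
    if (i <= la && j <= lb) {
      best <- max(best, S[ca[i], cb[j]] + rec(i + 1, j + 1, "m"))
    }
    if (i <= la) {
      cost <- if (last == "x") ext else open + ext
      best <- max(best, cost + rec(i + 1, j, "x"))
    }
    if (j <= lb) {
      cost <- if (last == "y") ext else open + ext
      best <- max(best, cost + rec(i, j + 1, "y"))
    }
    best
  }
  rec(1, 1, "m")
}

# a random tree with known positive edge lengths plus its exact path-length
# (additive) distance matrix
random_additive_case <- function(n, seed) {
  tr <- markertree::simulate_species_tree(n, depth = 1, seed = seed)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 2)
  D <- ape::cophenetic.phylo(tr)
  list(tree = tr, D = D)
}

# hand-built domtblout text in the documented 23-column layout
domtblout_fixture_text <- function() {
  c("#                         --- full sequence ---",
    "# target name  accession  tlen query name  accession  qlen  E-value  score  bias ...",
    paste("geneA -  632 HSP70 PF00012.20  609  1.2e-30 210.5  0.1",
          "1 2 1.1e-31 1.4e-28 118.9 0.0 3 330 4 340 2 350 0.92 chaperone"),
    paste("geneA -  632 OtherDom PF00099.7  120  2.0e-05  20.1  0.0",
          "1 1 2e-05 2e-05 19.0 0.0 1 100 1 100 1 100 0.80 -"),
    paste("geneB -  200 RiboS7 -  155  3.3e-12  88.0  0.0",
          "1 1 3e-12 3e-12 87.0 0.0 1 150 5 160 1 170 0.95 ribosomal"),
    "#")
}
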
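# Internal helpers: genotype normalisation, transmitted-allele resolution,
# and phase-matrix construction shared by the grouping/ordering modules.

.normGeno <- function(g) {
  if (is.na(g) || g == "--" || g == "") return("--")
  ch <- sort(strsplit(g, "")[[1]])
  paste(ch, collapse = "")
}

.isHet <- function(g) g != "--" & substr(g, 1, 1) != substr(g, 2, 2)
.isMissing <- function(g) g == "--"

# Which allele did the het parent transmit, given the other parent's
# genotype? Returns the allele character, or NA if the progeny genotype is
# Mendelian-inconsistent or unresolvable.
.transmitted <- function(progeny, hetAlleles, otherGeno) {
  if (progeny == "--") return(NA_character_)
  pg <- strsplit(progeny, "")[[1]]
  oth <- strsplit(otherGeno, "")[[1]]
  # other parent homozygous: remove one copy of its allele, remainder came
  # from the het parent
  o <- oth[1]
  i <- match(o, pg)
  if (is.na(i)) return(NA_character_)
  rest <- pg[-i]
  if (rest %in% hetAlleles) rest else NA_character_
}

# Phase matrix for one parent: markers x progeny, values 0/1/NA.
# Phase 0 corresponds to the first (sorted) allele of the parent's genotype.
# Single-parent-informative markers: all called progeny are phased.
# Double-heterozygote (DH) markers: only progeny homozygous at the marker
# are phase-resolvable (the hom allele was transmitted by both parents).
.phaseMatrix <- function(table, parent, markers) {
  g <- progenyGenotypes(table)[markers, , drop = FALSE]
  pf <- parentGenotypes(table, "female")[markers]
  pm <- parentGenotypes(table, "male")[markers]
  het <- if (parent == "female") pf else pm
  oth <- if (parent == "female") pm else pf
  out <- matrix(NA_integer_, nrow = length(markers), ncol = ncol(g),
                dimnames = list(markers, colnames(g)))
  for (i in seq_along(markers)) {
    al <- strsplit(het[i], "")[[1]]
    if (al[1] == al[2]) next  # parent not heterozygous: no phase information
    if (.isHet(oth[i])) {
      # DH marker: hom progeny only
      hom <- !.isMissing(g[i, ]) & substr(g[i, ], 1, 1) == substr(g[i, ], 2, 2)
      a1 <- substr(g[i, ], 1, 1)
      ph <- ifelse(hom & a1 == al[1], 0L, ifelse(hom & a1 == al[2], 1L, NA))
      out[i, ] <- as.integer(ph)
    } else {
      tr <- vapply(g[i, ], .transmitted, character(1),
                   hetAlleles = al, otherGeno = oth[i])
      out[i, ] <- ifelse(is.na(tr), NA_integer_,
                         ifelse(tr == al[1], 0L, 1L))
    }
  }
  out
}

# transmitted-allele matrix (characters) for one parent; NA if unresolvable
.alleleMatrix <- function(table, parent, markers) {
  ph <- .phaseMatrix(table, parent, markers)
  het <- parentGenotypes(table, parent)[markers]
  out <- matrix(NA_character_, nrow = nrow(ph), ncol = ncol(ph),
                dimnames = dimnames(ph))
  for (i in seq_len(nrow(ph))) {
    al <- strsplit(het[i], "")[[1]]
    out[i, ] <- ifelse(is.na(ph[i, ]), NA_character_, al[ph[i, ] + 1L])
  }
  out
}

# all permutations of seq_len(n), as a matrix with one permutation per row
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

.canonicalOrder <- function(ids) {
  rev_ids <- rev(ids)
  if (paste(ids, collapse = "\r") <= paste(rev_ids, collapse = "\r"))
    ids else rev_ids
}
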
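#' @include AllClasses.R params.R
NULL

## bead ordering convention: residue 1 contributes S,B; residues 2..N
## contribute P,S,B. Total 3N-1 beads.

#' Bead index lookup table
#'
#' @param n number of nucleotides.
#' @return Integer matrix (n x 3) with columns P, S, B giving the bead index
#'   of each site of each residue (P of residue 1 is NA).
#' @export
beadIndices <- function(n) {
  m <- matrix(NA_integer_, n, 3, dimnames = list(NULL, c("P", "S", "B")))
  m[1, "S"] <- 1L; m[1, "B"] <- 2L
  if (n > 1) {
    i <- 2:n
    m[i, "P"] <- 3L * (i - 1L)
    m[i, "S"] <- 3L * (i - 1L) + 1L
    m[i, "B"] <- 3L * (i - 1L) + 2L
  }
  m
}

#' Is a base combination a canonical or wobble pair?
#'
#' Canonical Watson-Crick (G-C, A-U) and wobble (G-U) combinations.
#'
#' @param a,b nucleotide letters.
#' @return Logical.
#' @export
isComplementary <- function(a, b) {
  paste0(a, b) %in% c("GC", "CG", "AU", "UA", "GU", "UG")
}

## construct a CGSystem from sequence + bead coordinates (nm)
newCGSystem <- function(sequence, coords, boxEdge = Inf,
                        numberingOffset = 1L, params = tisParams()) {
  n <- length(sequence)
  bidx <- beadIndices(n)
  nb <- 3L * n - 1L
  stopifnot(nrow(coords) == nb)
  type <- character(nb); res <- integer(nb)
  for (r in seq_len(n)) for (tp in c("P", "S", "B")) {
    k <- bidx[r, tp]
    if (!is.na(k)) { type[k] <- tp; res[k] <- r }
  }
  radius <- ifelse(type == "P", params$radii[["P"]],
            ifelse(type == "S", params$radii[["S"]],
                   unname(params$radii[sequence[res]])))
  charge <- ifelse(type == "P", -1, 0)
  if (is.finite(boxEdge)) coords <- coords - boxEdge * floor(coords / boxEdge)
  new("CGSystem", sequence = sequence, beadCoords = unname(coords),
      beadResidue = res, beadType = type, beadCharge = charge,
      beadRadius = unname(radius),
      ionCoords = matrix(numeric(), 0, 3), ionSpecies = character(),
      ionCharge = numeric(), ionRadius = numeric(),
      boxEdge = boxEdge, numberingOffset = as.integer(numberingOffset))
}

.pairdist <- function(coords, i, j) {
  sqrt(sum((coords[i, ] - coords[j, ])^2))
}

.angleOf <- function(coords, a, b, c) {
  u <- coords[a, ] - coords[b, ]; v <- coords[c, ] - coords[b, ]
  ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, ct)))
}

#' Build a Go-style interaction registry from a native frame
#'
#' Derives the bonded topology (bonds and angles with natural values
#' measured from the native coordinates), the consecutive-nucleotide stack
#' list, native secondary base pairs with their natural base-base distances
#' and flanking sugar-base-base angles, and optional tertiary hydrogen
#' bonds/stacks, elements, segments and Mg2+-site annotations.
#'
#' @param system a [CGSystem-class].
#' @param nativeCoords native bead coordinates (nm); defaults to the
#'   system's coordinates.
#' @param pairs data.frame(resI, resJ, helix) of native secondary pairs.
#' @param tertiaryHB optional data.frame(i, j, label) of bead-index pairs.
#' @param tertiaryStacks optional data.frame(i, j, label) of bead-index pairs.
#' @param elements named list; each entry a list with any of `pairs`
#'   (row indices into `pairs`), `hb`, `stacks`.
#' @param segments named list of residue-index vectors.
#' @param mgSites integer residue indices observed to bind Mg2+.
#' @return An [InteractionRegistry-class].
#' @export
buildRegistry <- function(system, nativeCoords = beadCoords(system),
                          pairs = data.frame(resI = integer(), resJ = integer(),
                                             helix = character()),
                          tertiaryHB = NULL, tertiaryStacks = NULL,
                          elements = list(), segments = list(),
                          mgSites = integer()) {
  n <- nNucleotides(system)
  bidx <- beadIndices(n)
  X <- nativeCoords
  bonds <- list(); angles <- list()
  for (r in seq_len(n)) {
    S <- bidx[r, "S"]; B <- bidx[r, "B"]; P <- bidx[r, "P"]
    bonds[[length(bonds) + 1L]] <- c(S, B)
    if (!is.na(P)) bonds[[length(bonds) + 1L]] <- c(P, S)
    if (r < n) {
      Pn <- bidx[r + 1L, "P"]; Sn <- bidx[r + 1L, "S"]
      bonds[[length(bonds) + 1L]] <- c(S, Pn)
      angles[[length(angles) + 1L]] <- c(B, S, Pn)
      if (!is.na(P)) angles[[length(angles) + 1L]] <- c(P, S, Pn)
      angles[[length(angles) + 1L]] <- c(S, Pn, Sn)
    }
    if (!is.na(P)) angles[[length(angles) + 1L]] <- c(P, S, B)
  }
  bm <- do.call(rbind, bonds)
  bonds <- data.frame(i = bm[, 1], j = bm[, 2],
                      r0 = vapply(seq_len(nrow(bm)), function(k)
                        .pairdist(X, bm[k, 1], bm[k, 2]), 0))
  if (length(angles)) {
    am <- do.call(rbind, angles)
    angles <- data.frame(i = am[, 1], j = am[, 2], k = am[, 3],
                         theta0 = vapply(seq_len(nrow(am)), function(k)
                           .angleOf(X, am[k, 1], am[k, 2], am[k, 3]), 0))
  } else {
    angles <- data.frame(i = integer(), j = integer(), k = integer(),
                         theta0 = numeric())
  }
  ## consecutive stacks
  if (n > 1L) {
    st <- data.frame(i = bidx[seq_len(n - 1L), "B"], j = bidx[2:n, "B"])
    st$r0 <- vapply(seq_len(nrow(st)), function(k)
      .pairdist(X, st$i[k], st$j[k]), 0)
    st$tertiary <- FALSE
    st$label <- paste0("st", seq_len(n - 1L))
  } else {
    st <- data.frame(i = integer(), j = integer(), r0 = numeric(),
                     tertiary = logical(), label = character())
  }
  if (!is.null(tertiaryStacks) && nrow(tertiaryStacks)) {
    ts <- data.frame(i = tertiaryStacks$i, j = tertiaryStacks$j,
                     r0 = vapply(seq_len(nrow(tertiaryStacks)), function(k)
                       .pairdist(X, tertiaryStacks$i[k], tertiaryStacks$j[k]), 0),
                     tertiary = TRUE,
                     label = as.character(tertiaryStacks$label))
    st <- rbind(st, ts)
  }
  ## native secondary pairs: natural base-base distance + flank angles
  sp <- pairs
  if (nrow(sp)) {
    sq <- rnaSequence(system)
    ok <- mapply(isComplementary, sq[sp$resI], sq[sp$resJ])
    if (!all(ok))
      stop("non-complementary native pair(s): ",
           paste(which(!ok), collapse = ","))
    sp$r0 <- vapply(seq_len(nrow(sp)), function(k)
      .pairdist(X, bidx[sp$resI[k], "B"], bidx[sp$resJ[k], "B"]), 0)
    sp$theta1 <- vapply(seq_len(nrow(sp)), function(k)
      .angleOf(X, bidx[sp$resI[k], "S"], bidx[sp$resI[k], "B"],
               bidx[sp$resJ[k], "B"]), 0)
    sp$theta2 <- vapply(seq_len(nrow(sp)), function(k)
      .angleOf(X, bidx[sp$resI[k], "B"], bidx[sp$resJ[k], "B"],
               bidx[sp$resJ[k], "S"]), 0)
  } else {
    sp <- data.frame(resI = integer(), resJ = integer(), helix = character(),
                     r0 = numeric(), theta1 = numeric(), theta2 = numeric())
  }
  thb <- if (!is.null(tertiaryHB) && nrow(tertiaryHB)) {
    data.frame(i = tertiaryHB$i, j = tertiaryHB$j,
               r0 = vapply(seq_len(nrow(tertiaryHB)), function(k)
                 .pairdist(X, tertiaryHB$i[k], tertiaryHB$j[k]), 0),
               label = as.character(tertiaryHB$label))
  } else data.frame(i = integer(), j = integer(), r0 = numeric(),
                    label = character())
  new("InteractionRegistry", bonds = bonds, angles = angles,
      secondaryPairs = sp, tertiaryHB = thb, stacks = st,
      elements = elements, segments = segments,
      mgSites = as.integer(mgSites))
}

## Watson-Crick edge heavy atoms used for geometric pair detection
.wcAtoms <- list(A = c("N1", "N6"), U = c("N3", "O2", "O4"),
                 G = c("N1", "N2", "O6"), C = c("N3", "O2", "N4"))

#' Coarse-grain an all-atom RNA structure
#'
#' Maps each nucleotide of one RNA chain in a PDB record to three beads: P
#' at the phosphorus atom, S at the sugar C4' atom, B at the centre of
#' geometry of the base heavy atoms. Residue numbering is preserved via
#' `numberingOffset`. Native secondary base pairs are detected
#' geometrically on the all-atom structure: two complementary residues are
#' paired when at least `minHBonds` Watson-Crick-edge heavy-atom pairs lie
#' within `hbDistance`; consecutive detected pairs are grouped into
#' helices. Remaining base-base contacts satisfying the same geometric
#' criterion but not complementary (or below the separation limit) are
#' registered as tertiary hydrogen bonds between base beads.
#'
#' @param pdb a file path or a `bio3d` pdb object.
#' @param chain chain identifier; default: the first chain in the file.
#' @param hbDistance donor/acceptor heavy-atom cutoff in nm (default 0.35).
#' @param minHBonds minimum number of in-range atom pairs (default 2).
#' @param params a [tisParams()] list (bead radii).
#' @return A list with elements `system` ([CGSystem-class]) and
#'   `registry` ([InteractionRegistry-class]).
#' @export
coarseGrainPDB <- function(pdb, chain = NULL, hbDistance = 0.35,
                           minHBonds = 2L, params = tisParams()) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  at <- pdb$atom
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain & at$type == "ATOM", , drop = FALSE]
  rn <- toupper(trimws(at$resid))
  map <- c(A = "A", U = "U", G = "G", C = "C", RA = "A", RU = "U",
           RG = "G", RC = "C")
  if (!all(rn %in% names(map)))
    stop("chain ", chain, " contains non-RNA residues: ",
         paste(unique(rn[!rn %in% names(map)]), collapse = ","))
  at$resid <- unname(map[rn])
  at <- at[!grepl("^H", trimws(at$elety)), , drop = FALSE]  # heavy atoms only
  resnos <- unique(at$resno)
  backboneNames <- c("P", "OP1", "OP2", "O1P", "O2P", "OP3", "O3P")
  seqs <- character(); pPos <- list(); sPos <- list(); bPos <- list()
  wc <- list(); keptResno <- integer()
  for (rno in resnos) {
    sub <- at[at$resno == rno, , drop = FALSE]
    nm <- trimws(sub$elety)
    letter <- sub$resid[1]
    sugar <- which(nm == "C4'")
    baseAt <- which(!grepl("'", nm) & !(nm %in% backboneNames))
    if (length(sugar) != 1L || length(baseAt) == 0L) {
      warning("residue ", rno, " rejected: missing sugar or base atoms")
      next
    }
    pAt <- which(nm == "P")
    keptResno <- c(keptResno, rno)
    seqs <- c(seqs, letter)
    k <- length(seqs)
    pPos[[k]] <- if (length(pAt) == 1L)
      as.numeric(sub[pAt, c("x", "y", "z")]) / 10 else NULL
    sPos[[k]] <- as.numeric(sub[sugar, c("x", "y", "z")]) / 10
    bPos[[k]] <- colMeans(sub[baseAt, c("x", "y", "z")]) / 10
    wcNames <- .wcAtoms[[letter]]
    wcRows <- which(nm %in% wcNames)
    wc[[k]] <- as.matrix(sub[wcRows, c("x", "y", "z")]) / 10
  }
  n <- length(seqs)
  if (n < 2L) stop("fewer than 2 usable residues in chain ", chain)
  ## any phosphate on the first residue is dropped: the 5' terminal
  ## nucleotide carries no P bead
  bidx <- beadIndices(n)
  coords <- matrix(NA_real_, 3L * n - 1L, 3)
  for (r in seq_len(n)) {
    if (r > 1L) {
      coords[bidx[r, "P"], ] <- if (!is.null(pPos[[r]])) pPos[[r]] else {
        warning("residue ", keptResno[r], " lacks P; bead placed at sugar")
        sPos[[r]]
      }
    }
    coords[bidx[r, "S"], ] <- sPos[[r]]
    coords[bidx[r, "B"], ] <- bPos[[r]]
  }
  system <- newCGSystem(seqs, coords, boxEdge = Inf,
                        numberingOffset = keptResno[1], params = params)
  ## geometric base-pair detection on the all-atom WC edges
  hits <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    wi <- wc[[i]]; wj <- wc[[j]]
    if (!length(wi) || !length(wj)) next
    d <- sqrt(outer(rowSums(wi^2), rowSums(wj^2), "+") - 2 * wi %*% t(wj))
    nhb <- sum(d < hbDistance)
    if (nhb >= minHBonds)
      hits[[length(hits) + 1L]] <- c(i, j, isComplementary(seqs[i], seqs[j]))
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    matrix(integer(), 0, 3)
  sec <- hits[hits[, 3] == 1 & (hits[, 2] - hits[, 1]) >= 4, , drop = FALSE]
  ter <- hits[!(hits[, 3] == 1 & (hits[, 2] - hits[, 1]) >= 4), , drop = FALSE]
  pairs <- data.frame(resI = integer(), resJ = integer(), helix = character())
  if (nrow(sec)) {
    ## group consecutive pairs (i+1, j-1 follows i, j) into helices
    ord <- order(sec[, 1])
    sec <- sec[ord, , drop = FALSE]
    helix <- integer(nrow(sec))
    h <- 0L
    key <- paste(sec[, 1], sec[, 2])
    for (k in seq_len(nrow(sec))) {
      prev <- which(key == paste(sec[k, 1] - 1L, sec[k, 2] + 1L))
      helix[k] <- if (length(prev)) helix[prev[1]] else (h <- h + 1L)
    }
    pairs <- data.frame(resI = sec[, 1], resJ = sec[, 2],
                        helix = paste0("H", helix))
  }
  thb <- NULL
  if (nrow(ter)) {
    thb <- data.frame(i = bidx[ter[, 1], "B"], j = bidx[ter[, 2], "B"],
                      label = paste0("t", ter[, 1], "-", ter[, 2]))
  }
  registry <- buildRegistry(system, pairs = pairs, tertiaryHB = thb)
  list(system = system, registry = registry)
}

#' Enumerate complementary antiparallel segment pairs
#'
#' Scans a sequence for maximal antiparallel duplexes: runs of pairwise
#' canonical/wobble complementary positions (i, j), (i+1, j-1), ... of
#' length at least `minLength`. These are the candidate helices, native and
#' mispaired, that the chain can form while strands search for their
#' partners.
#'
#' @param sequence character vector of nucleotide letters.
#' @param minLength minimum run length (>= 2).
#' @param registry optional [InteractionRegistry-class]; duplexes matching
#'   registered native pairs are flagged native.
#' @return data.frame(start1, end1, start2, end2, length, native).
#' @export
enumerateComplementarySegments <- function(sequence, minLength = 4L,
                                           registry = NULL) {
  stopifnot(minLength >= 2)
  n <- length(sequence)
  comp <- function(i, j) i >= 1 && j <= n && j - i >= 2 &&
    isComplementary(sequence[i], sequence[j])
  natKey <- character()
  if (!is.null(registry) && nrow(registry@secondaryPairs))
    natKey <- paste(registry@secondaryPairs$resI, registry@secondaryPairs$resJ)
  out <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i || !comp(i, j)) next
    if (comp(i - 1L, j + 1L)) next       # not the start of a maximal run
    L <- 0L
    while (comp(i + L, j - L)) L <- L + 1L
    if (L < minLength) next
    pk <- paste(i + seq_len(L) - 1L, j - seq_len(L) + 1L)
    out[[length(out) + 1L]] <- data.frame(
      start1 = i, end1 = i + L - 1L, start2 = j - L + 1L, end2 = j,
      length = L, native = length(natKey) > 0 && all(pk %in% natKey))
  }
  if (!length(out))
    return(data.frame(start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer(),
                      length = integer(), native = logical()))
  do.call(rbind, out)
}

#' Serialize a coarse-grained topology to JSON
#'
#' Writes the system (sequence, bead and ion coordinates at full precision,
#' box, numbering) and the interaction registry to a single JSON file;
#' `readTopology` reconstructs both objects bit-exactly.
#'
#' @param system a [CGSystem-class].
#' @param registry an [InteractionRegistry-class].
#' @param path output file.
#' @return `readTopology` returns list(system, registry).
#' @export
writeTopology <- function(system, registry, path) {
  ## coordinates as %.17g strings: doubles round-trip bit-exactly
  num17 <- function(x) matrix(sprintf("%.17g", x), nrow(x), ncol(x))
  enc <- list(
    sequence = system@sequence,
    beadCoords = num17(system@beadCoords),
    ionCoords = num17(system@ionCoords),
    ionSpecies = system@ionSpecies,
    ionCharge = system@ionCharge,
    ionRadius = system@ionRadius,
    beadCharge = system@beadCharge,
    beadRadius = system@beadRadius,
    boxEdge = if (is.finite(system@boxEdge)) system@boxEdge else "Inf",
    numberingOffset = system@numberingOffset,
    registry = list(
      bonds = registry@bonds, angles = registry@angles,
      secondaryPairs = registry@secondaryPairs,
      tertiaryHB = registry@tertiaryHB, stacks = registry@stacks,
      elements = registry@elements, segments = registry@segments,
      mgSites = registry@mgSites))
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname writeTopology
#' @export
readTopology <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  box <- if (identical(x$boxEdge, "Inf")) Inf else as.numeric(x$boxEdge)
  n <- length(x$sequence)
  sys <- newCGSystem(x$sequence,
                     matrix(as.numeric(x$beadCoords), 3L * n - 1L, 3),
                     boxEdge = box,
                     numberingOffset = as.integer(x$numberingOffset))
  sys@beadCharge <- as.numeric(x$beadCharge)
  sys@beadRadius <- as.numeric(x$beadRadius)
  if (length(x$ionSpecies)) {
    sys@ionCoords <- matrix(as.numeric(x$ionCoords),
                            length(x$ionSpecies), 3)
    sys@ionSpecies <- as.character(x$ionSpecies)
    sys@ionCharge <- as.numeric(x$ionCharge)
    sys@ionRadius <- as.numeric(x$ionRadius)
  }
  validObject(sys)
  r <- x$registry
  asdf <- function(d, cols) {
    d <- as.data.frame(d, stringsAsFactors = FALSE)
    if (!nrow(d) && !all(cols %in% names(d)))
      d <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)),
                                         cols))
    d
  }
  els <- lapply(r$elements, function(e) lapply(e, as.integer))
  reg <- new("InteractionRegistry",
             bonds = asdf(r$bonds, c("i", "j", "r0")),
             angles = asdf(r$angles, c("i", "j", "k", "theta0")),
             secondaryPairs = asdf(r$secondaryPairs,
                                   c("resI", "resJ", "helix", "r0",
                                     "theta1", "theta2")),
             tertiaryHB = asdf(r$tertiaryHB, c("i", "j", "r0", "label")),
             stacks = asdf(r$stacks, c("i", "j", "r0", "tertiary", "label")),
             elements = els,
             segments = lapply(r$segments, as.integer),
             mgSites = as.integer(r$mgSites))
  validObject(reg)
  list(system = sys, registry = reg)
}
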
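# Shared fixtures, built lazily once per test run.
suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(SingleCellExperiment)
})

.fx <- new.env()

# small 2-species development panel (fast; used by several module tests)
fxSmallPanel <- function() {
    if (is.null(.fx$small)) {
        cfg <- synthConfig(nSpecies = 2, cellsPerDataset = 200, nGenes = 500,
                           sharedTypes = c(AER = 0.2, CT = 0.4, Muscle = 0.4),
                           privateTypes = list(species1 = "Goblet"),
                           nPrivateGenes = 10, transcriptDupSpecies = 0,
                           seed = 7)
        .fx$small <- generateDevelopmentPanel(cfg)
    }
    .fx$small
}

# normalized version of the small panel (shared gene space)
fxSmallNormalized <- function() {
    if (is.null(.fx$small_norm)) {
        panel <- fxSmallPanel()
        collapsed <- lapply(panel$datasets, collapseDuplicates,
                            orth = panel$orthology)
        shared <- buildSharedSpace(collapsed)
        .fx$small_norm <- lapply(shared, normalizeSelectHVG, nHVG = 300)
    }
    .fx$small_norm
}

# brute-force neighbour-voting AUROC oracle: same network construction,
# explicit pair counting with half credit for ties
oracleNeighborVoting <- function(features, datasets, clusters) {
    n <- ncol(features)
    rk <- apply(features, 2, rank)
    cors <- suppressWarnings(cor(rk))
    diag(cors) <- NA
    conn <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) {
        r <- rank(cors[i, ], ties.method = "average", na.last = "keep")
        conn[i, ] <- r / max(r, na.rm = TRUE)
    }
    pairs <- unique(data.frame(ds = datasets, cl = clusters,
                               stringsAsFactors = FALSE))
    pairs <- pairs[order(pairs$ds, pairs$cl), ]
    labs <- paste(pairs$ds, pairs$cl, sep = "|")
    out <- matrix(NA_real_, nrow(pairs), nrow(pairs), dimnames = list(labs, labs))
    diag(out) <- 1
    direction <- function(i, j) {
        train <- which(datasets == pairs$ds[i] & clusters == pairs$cl[i])
        test <- which(datasets == pairs$ds[j])
        votes <- rowMeans(conn[test, train, drop = FALSE], na.rm = TRUE)
        pos <- votes[clusters[test] == pairs$cl[j]]
        neg <- votes[clusters[test] != pairs$cl[j]]
        if (!length(pos) || !length(neg)) return(NA_real_)
        tot <- 0
        for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
        tot / (length(pos) * length(neg))
    }
    for (i in seq_len(nrow(pairs) - 1)) {
        for (j in seq(i + 1, nrow(pairs))) {
            if (pairs$ds[i] == pairs$ds[j]) next
            out[i, j] <- out[j, i] <- mean(c(direction(i, j), direction(j, i)))
        }
    }
    out
}

# brute-force AUCell recovery-curve oracle
oracleAucell <- function(counts, set, topFraction) {
    nG <- nrow(counts)
    top <- ceiling(topFraction * nG)
    k <- sum(rownames(counts) %in% set)
    max_auc <- sum(pmin(seq_len(top), k))
    vapply(seq_len(ncol(counts)), function(j) {
        ord <- order(-counts[, j], seq_len(nG))
        hits <- rownames(counts)[ord] %in% set
        sum(cumsum(hits)[seq_len(top)]) / max_auc
    }, 0)
}

# exact two-sided rank-sum p value by enumeration of all group assignments
oracleExactRankSum <- function(a, b) {
    pooled <- c(a, b)
    nA <- length(a)
    N <- length(pooled)
    mu <- nA * (N - nA) / 2
    ustat <- function(idx) {
        r <- rank(pooled)
        sum(r[idx]) - nA * (nA + 1) / 2
    }
    u_obs <- ustat(seq_len(nA))
    combs <- utils::combn(N, nA)
    us <- apply(combs, 2, ustat)
    mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# hand BH formula
oracleBH <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m)
    out[o] <- pmin(adj, 1)
    out
}

# log-normalized matrix helper for raw SCEs
logNorm <- function(m) {
    counts <- as.matrix(assay(m, "counts"))
    tot <- pmax(colSums(counts), 1)
    log1p(sweep(counts, 2, tot, "/") * 1e4)
}
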
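#' Configuration for the synthetic multi-species limb data generator
#'
#' Builds a validated configuration describing the simulated study: a panel
#' of species-level droplet scRNA-seq datasets with shared cell types, one
#' species-private type (a goblet-cell analogue), a pseudo-tetraploid
#' species whose genes appear as L/S homeolog row pairs, a cell-cycle
#' confound, an AER expression program planted in ectodermal cells, and (in
#' regeneration mode) a partial AER program planted in a subset of
#' connective-tissue cells. Counts follow a negative binomial (gamma-Poisson)
#' model with per-cell log-normal library-size factors.
#'
#' All effect sizes are natural-log fold changes applied multiplicatively to
#' the gene's mean before depth normalization.
#'
#' @param nSpecies number of species (one development dataset each).
#' @param cellsPerDataset cells per generated dataset.
#' @param nGenes number of shared gene symbols in the universe.
#' @param sharedTypes named numeric vector of shared cell-type proportions
#'   (must include "AER" for the development panel; proportions sum to 1).
#' @param privateTypes named list mapping species name to a private type
#'   name (the goblet analogue); may be empty.
#' @param privateTypeProp proportion of cells given to a species' private
#'   type (shared types are rescaled to the remainder).
#' @param aerProgramGenes number of genes in the planted AER program.
#' @param aerEffect log-fold mean shift of program genes in AER/AEC cells.
#' @param markersPerType marker genes per non-AER cell type.
#' @param typeEffect log-fold mean shift of a type's markers in that type.
#' @param homeologSpecies index of the pseudo-tetraploid species whose
#'   homeolog genes are emitted as `SYM.L`/`SYM.S` row pairs (0 = none).
#' @param homeologGenes number of symbols emitted as homeolog pairs.
#' @param homeologSplit fraction of a homeolog gene's mean assigned to the
#'   L copy (the S copy receives the remainder).
#' @param transcriptDupSpecies index of the species with duplicate
#'   transcript rows `SYM.t1`/`SYM.t2` (0 = none).
#' @param transcriptDupGenes number of duplicated-transcript symbols.
#' @param transcriptSplit fraction of the mean assigned to `.t1`.
#' @param cycleGenes number of cell-cycle genes (half S-phase, half G2M).
#' @param cycleStrength log-fold shift of phase genes in cycling cells.
#' @param cyclingFraction proportion of cycling cells per dataset.
#' @param ctProgramFraction regeneration mode: proportion of CT cells
#'   carrying the partial AER program.
#' @param aecOverlap fraction of the AER program shared by the AEC type
#'   (the remaining program genes, an FGF-ligand-like tail, are dropped).
#' @param ctProgramOverlap fraction of the AER program carried by
#'   program-positive CT cells (a subset of the AEC overlap, headed by the
#'   designated epithelial markers).
#' @param epithelialMarkers number of leading program genes treated as
#'   epithelial markers.
#' @param negativeControl if `TRUE`, the dataset of
#'   `negativeControlSpecies` contains no AER cells.
#' @param negativeControlSpecies species index for the negative control.
#' @param nPrivateGenes species-private gene symbols per species (present
#'   only in that species' feature space).
#' @param nbDispersion negative binomial dispersion phi
#'   (variance = mu + phi * mu^2).
#' @param depthMean expected total counts per cell.
#' @param depthSigma sdlog of the per-cell log-normal library-size factor.
#' @param timepoints labels of the regeneration time-course datasets.
#' @param gridNrow,gridNcol spatial section grid dimensions.
#' @param cellsPerSpot synthetic cells summed into each spatial spot.
#' @param seed integer seed governing all randomness.
#'
#' @return an object of class `"SynthConfig"` (a validated named list).
#' @examples
#' cfg <- synthConfig(nSpecies = 2, cellsPerDataset = 100, nGenes = 500)
#' panel <- generateDevelopmentPanel(cfg)
#' @export
synthConfig <- function(nSpecies = 5L,
                        cellsPerDataset = 800L,
                        nGenes = 1200L,
                        sharedTypes = c(AER = 0.10, BasalEctoderm = 0.20,
                                        CT = 0.30, Muscle = 0.25,
                                        Immune = 0.15),
                        privateTypes = NULL,
                        privateTypeProp = 0.10,
                        aerProgramGenes = 100L,
                        aerEffect = 2.0,
                        markersPerType = 40L,
                        typeEffect = 2.0,
                        homeologSpecies = NULL,
                        homeologGenes = 200L,
                        homeologSplit = 0.7,
                        transcriptDupSpecies = 1L,
                        transcriptDupGenes = 100L,
                        transcriptSplit = 0.6,
                        cycleGenes = 60L,
                        cycleStrength = 1.0,
                        cyclingFraction = 0.2,
                        ctProgramFraction = 0.3,
                        aecOverlap = 0.6,
                        ctProgramOverlap = 0.6,
                        epithelialMarkers = 10L,
                        negativeControl = FALSE,
                        negativeControlSpecies = nSpecies,
                        nPrivateGenes = 50L,
                        nbDispersion = 0.25,
                        depthMean = 5000,
                        depthSigma = 0.3,
                        timepoints = c("3dpa", "8dpa", "14dpa"),
                        gridNrow = 20L,
                        gridNcol = 20L,
                        cellsPerSpot = 8L,
                        seed = 7L) {
    species <- if (nSpecies == 5L) {
        c("axolotl", "human", "mouse", "chicken", "frog")
    } else {
        paste0("species", seq_len(nSpecies))
    }
    if (is.null(homeologSpecies))
        homeologSpecies <- if (nSpecies == 5L) 5L else 0L
    if (is.null(privateTypes))
        privateTypes <- stats::setNames(list("Goblet"), species[1])
    privateTypes <- privateTypes[names(privateTypes) %in% species]

    cfg <- list(
        nSpecies = as.integer(nSpecies), species = species,
        cellsPerDataset = as.integer(cellsPerDataset),
        nGenes = as.integer(nGenes),
        sharedTypes = sharedTypes, privateTypes = privateTypes,
        privateTypeProp = privateTypeProp,
        aerProgramGenes = as.integer(aerProgramGenes), aerEffect = aerEffect,
        markersPerType = as.integer(markersPerType), typeEffect = typeEffect,
        homeologSpecies = as.integer(homeologSpecies),
        homeologGenes = as.integer(homeologGenes), homeologSplit = homeologSplit,
        transcriptDupSpecies = as.integer(transcriptDupSpecies),
        transcriptDupGenes = as.integer(transcriptDupGenes),
        transcriptSplit = transcriptSplit,
        cycleGenes = as.integer(cycleGenes), cycleStrength = cycleStrength,
        cyclingFraction = cyclingFraction,
        ctProgramFraction = ctProgramFraction,
        aecOverlap = aecOverlap, ctProgramOverlap = ctProgramOverlap,
        epithelialMarkers = as.integer(epithelialMarkers),
        negativeControl = isTRUE(negativeControl),
        negativeControlSpecies = as.integer(negativeControlSpecies),
        nPrivateGenes = as.integer(nPrivateGenes),
        nbDispersion = nbDispersion,
        depthMean = depthMean, depthSigma = depthSigma,
        timepoints = timepoints,
        gridNrow = as.integer(gridNrow), gridNcol = as.integer(gridNcol),
        cellsPerSpot = as.integer(cellsPerSpot),
        seed = .check_seed(seed)
    )
    class(cfg) <- "SynthConfig"
    .validate_config(cfg)
    cfg
}

.validate_config <- function(cfg) {
    props <- c(cfg$cyclingFraction, cfg$ctProgramFraction, cfg$aecOverlap,
               cfg$ctProgramOverlap, cfg$privateTypeProp,
               cfg$homeologSplit, cfg$transcriptSplit)
    if (any(props < 0 | props > 1))
        stop("all proportions must lie in [0, 1]")
    if (abs(sum(cfg$sharedTypes) - 1) > 1e-8)
        stop("sharedTypes proportions must sum to 1")
    u <- .gene_universe(cfg)
    if (cfg$nGenes < cfg$aerProgramGenes + cfg$cycleGenes)
        stop("nGenes must be at least aerProgramGenes + cycleGenes")
    if (u$used > cfg$nGenes)
        stop("gene universe too small for the configured marker/cycle/private blocks (needs ",
             u$used, " of ", cfg$nGenes, " genes)")
    invisible(cfg)
}

# Deterministic role layout of the shared symbol universe (no RNG).
.gene_universe <- function(cfg) {
    symbols <- sprintf("G%04d", seq_len(cfg$nGenes))
    pos <- 0L
    take <- function(n) {
        idx <- pos + seq_len(n)
        pos <<- pos + n
        idx
    }
    program <- take(cfg$aerProgramGenes)
    marker_types <- setdiff(names(cfg$sharedTypes), "AER")
    marker_types <- unique(c(marker_types, unlist(cfg$privateTypes), "AEC"))
    markers <- lapply(marker_types, function(t) take(cfg$markersPerType))
    names(markers) <- marker_types
    cyc <- take(cfg$cycleGenes)
    cycleS <- cyc[seq_len(floor(cfg$cycleGenes / 2))]
    cycleG2M <- setdiff(cyc, cycleS)
    used_front <- pos
    private <- list()
    if (cfg$nPrivateGenes > 0) {
        for (i in seq_len(cfg$nSpecies)) {
            sp <- cfg$species[i]
            private[[sp]] <- cfg$nGenes - cfg$nSpecies * cfg$nPrivateGenes +
                (i - 1L) * cfg$nPrivateGenes + seq_len(cfg$nPrivateGenes)
        }
    }
    background <- setdiff(seq_len(cfg$nGenes),
                          c(seq_len(used_front), unlist(private)))
    nh <- min(cfg$homeologGenes, length(background))
    homeolog <- background[seq_len(nh)]
    rest <- setdiff(background, homeolog)
    nt <- min(cfg$transcriptDupGenes, length(rest))
    transcript <- rest[seq_len(nt)]
    list(symbols = symbols, program = program, markers = markers,
         cycleS = cycleS, cycleG2M = cycleG2M,
         private = private, homeolog = homeolog, transcript = transcript,
         used = used_front + cfg$nSpecies * cfg$nPrivateGenes)
}

# Type-by-gene mean profile matrix at symbol level (consumes RNG for the
# lognormal baseline).
.type_profiles <- function(cfg, u, types) {
    base <- stats::rlnorm(cfg$nGenes, meanlog = 0, sdlog = 1)
    prof <- matrix(rep(base, each = length(types)), nrow = length(types),
                   dimnames = list(types, u$symbols))
    for (t in types) {
        if (t == "AER") {
            prof[t, u$program] <- prof[t, u$program] * exp(cfg$aerEffect)
        } else if (t == "AEC") {
            ov <- u$program[seq_len(ceiling(cfg$aecOverlap * length(u$program)))]
            prof[t, ov] <- prof[t, ov] * exp(cfg$aerEffect)
            prof[t, u$markers[[t]]] <- prof[t, u$markers[[t]]] * exp(cfg$typeEffect)
        } else if (t %in% names(u$markers)) {
            prof[t, u$markers[[t]]] <- prof[t, u$markers[[t]]] * exp(cfg$typeEffect)
        }
    }
    prof
}

.lineage_of <- function(types) {
    ecto <- c("AER", "AEC", "BasalEctoderm", "Goblet", "Periderm")
    meso <- c("CT", "Muscle", "LimbBudMesoderm")
    ifelse(types %in% ecto, "ectoderm",
           ifelse(types %in% meso, "mesoderm", "other"))
}

# allocate n cells over named proportions, >=1 per type, deterministic
.allocate_cells <- function(n, props) {
    types <- names(props)
    if (n < length(types))
        stop("cellsPerDataset (", n, ") is smaller than the number of declared types (",
             length(types), "): short by ", length(types) - n, " cells")
    counts <- pmax(1L, floor(props / sum(props) * n))
    while (sum(counts) > n) {
        i <- which.max(counts)
        counts[i] <- counts[i] - 1L
    }
    while (sum(counts) < n) {
        i <- which.max(props / sum(props) * n - counts)
        counts[i] <- counts[i] + 1L
    }
    rep(types, counts)
}

# Simulate one dataset. Returns SCE plus the per-cell expected-mean info.
.simulate_dataset <- function(cfg, u, prof, dataset_id, species, type_props,
                              regen = FALSE, include_cells = NULL) {
    n <- if (is.null(include_cells)) cfg$cellsPerDataset else include_cells
    type <- .allocate_cells(n, type_props)
    n <- length(type)
    cycling <- rep(FALSE, n)
    n_cyc <- round(cfg$cyclingFraction * n)
    if (n_cyc > 0) cycling[sample.int(n, n_cyc)] <- TRUE
    phase <- rep("G1", n)
    if (n_cyc > 0)
        phase[which(cycling)] <- rep(c("S", "G2M"), length.out = n_cyc)

    carries <- type %in% c("AER", "AEC")
    if (regen && cfg$ctProgramFraction > 0) {
        ct <- which(type == "CT")
        n_carry <- round(cfg$ctProgramFraction * length(ct))
        if (n_carry > 0)
            carries[sample(ct, n_carry)] <- TRUE
    }

    # symbol-level expected means per cell
    lam <- t(prof)[, type, drop = FALSE]      # genes x cells
    if (cfg$cycleStrength != 0 && n_cyc > 0) {
        sidx <- which(phase == "S")
        gidx <- which(phase == "G2M")
        if (length(sidx))
            lam[u$cycleS, sidx] <- lam[u$cycleS, sidx] * exp(cfg$cycleStrength)
        if (length(gidx))
            lam[u$cycleG2M, gidx] <- lam[u$cycleG2M, gidx] * exp(cfg$cycleStrength)
    }
    ct_sub <- u$program[seq_len(round(cfg$ctProgramOverlap * length(u$program)))]
    ct_carriers <- which(carries & type == "CT")
    if (length(ct_carriers))
        lam[ct_sub, ct_carriers] <- lam[ct_sub, ct_carriers] * exp(cfg$aerEffect)

    # restrict to the species' feature space (drop other species' private genes)
    other_private <- unlist(u$private[setdiff(names(u$private), species)])
    keep <- setdiff(seq_len(cfg$nGenes), other_private)
    lam <- lam[keep, , drop = FALSE]
    rownames(lam) <- u$symbols[keep]

    # depth normalization with log-normal size factors (mean 1)
    sf <- stats::rlnorm(n, meanlog = -cfg$depthSigma^2 / 2, sdlog = cfg$depthSigma)
    lam <- sweep(lam, 2, colSums(lam), "/")
    lam <- sweep(lam, 2, cfg$depthMean * sf, "*")

    # expand duplicate rows (homeologs / transcripts) for this species
    sp_idx <- match(species, cfg$species)
    split_map <- NULL
    if (!regen) {
        if (!is.na(sp_idx) && sp_idx == cfg$homeologSpecies && length(u$homeolog))
            split_map <- list(idx = u$homeolog, tags = c("L", "S"),
                              frac = cfg$homeologSplit)
        else if (!is.na(sp_idx) && sp_idx == cfg$transcriptDupSpecies &&
                 length(u$transcript))
            split_map <- list(idx = u$transcript, tags = c("t1", "t2"),
                              frac = cfg$transcriptSplit)
    }
    if (!is.null(split_map)) {
        dup_syms <- u$symbols[split_map$idx]
        in_space <- intersect(dup_syms, rownames(lam))
        lam_dup1 <- lam[in_space, , drop = FALSE] * split_map$frac
        lam_dup2 <- lam[in_space, , drop = FALSE] * (1 - split_map$frac)
        rownames(lam_dup1) <- paste0(in_space, ".", split_map$tags[1])
        rownames(lam_dup2) <- paste0(in_space, ".", split_map$tags[2])
        lam <- rbind(lam[setdiff(rownames(lam), in_space), , drop = FALSE],
                     lam_dup1, lam_dup2)
    }

    counts <- matrix(stats::rnbinom(length(lam), mu = as.vector(lam),
                                    size = 1 / cfg$nbDispersion),
                     nrow = nrow(lam), dimnames = dimnames(lam))
    cell_ids <- sprintf("%s_c%04d", dataset_id, seq_len(n))
    colnames(counts) <- cell_ids
    truth <- DataFrame(
        cell_id = cell_ids, species = species, dataset_id = dataset_id,
        true_type = type, lineage = .lineage_of(type),
        cycling = cycling, phase = phase, carries_program = carries
    )
    sce <- SingleCellExperiment(assays = list(counts = counts), colData = truth)
    metadata(sce)$dataset <- dataset_id
    metadata(sce)$species <- species
    sce
}

# orthology table covering every source row of every species
.panel_orthology <- function(cfg, u) {
    rows <- list()
    for (i in seq_len(cfg$nSpecies)) {
        sp <- cfg$species[i]
        other_private <- unlist(u$private[setdiff(names(u$private), sp)])
        keep <- setdiff(seq_len(cfg$nGenes), other_private)
        syms <- u$symbols[keep]
        src <- syms
        tag <- rep("1", length(syms))
        dup <- NULL
        if (i == cfg$homeologSpecies && length(u$homeolog)) {
            dup <- list(idx = u$homeolog, tags = c("L", "S"))
        } else if (i == cfg$transcriptDupSpecies && length(u$transcript)) {
            dup <- list(idx = u$transcript, tags = c("t1", "t2"))
        }
        if (!is.null(dup)) {
            dup_syms <- intersect(u$symbols[dup$idx], syms)
            keep_single <- setdiff(syms, dup_syms)
            src <- c(keep_single,
                     paste0(dup_syms, ".", dup$tags[1]),
                     paste0(dup_syms, ".", dup$tags[2]))
            sym_out <- c(keep_single, dup_syms, dup_syms)
            tag <- c(rep("1", length(keep_single)),
                     rep(dup$tags[1], length(dup_syms)),
                     rep(dup$tags[2], length(dup_syms)))
        } else {
            sym_out <- syms
        }
        rows[[sp]] <- data.frame(source_gene_id = src, species = sp,
                                 shared_symbol = sym_out, group_tag = tag,
                                 stringsAsFactors = FALSE)
    }
    do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Generate the multi-species development panel
#'
#' One negative-binomial scRNA-seq dataset per species with shared cell
#' types (including AER), the configured species-private goblet analogue,
#' homeolog/duplicate-transcript row pairs for the configured species, a
#' cell-cycle confound and the planted AER program. Ground-truth labels are
#' stored in each dataset's `colData`.
#'
#' @param config a [synthConfig()].
#' @return a list with elements `datasets` (named list of
#'   `SingleCellExperiment`, one per species), `orthology` (source gene to
#'   shared symbol table), `genes` (role layout of the symbol universe:
#'   program, markers, cycle and private gene indices), `profiles`
#'   (type x symbol expected-mean matrix) and `config`.
#' @export
generateDevelopmentPanel <- function(config) {
    .validate_config(config)
    u <- .gene_universe(config)
    set.seed(config$seed)
    types_all <- names(config$sharedTypes)
    private_names <- unique(unlist(config$privateTypes))
    prof <- .type_profiles(config, u, unique(c(types_all, private_names, "AEC")))
    datasets <- list()
    for (i in seq_len(config$nSpecies)) {
        sp <- config$species[i]
        props <- config$sharedTypes
        if (config$negativeControl && i == config$negativeControlSpecies) {
            props <- props[setdiff(names(props), "AER")]
            props <- props / sum(props)
        }
        if (sp %in% names(config$privateTypes)) {
            pt <- config$privateTypes[[sp]]
            props <- c(props * (1 - config$privateTypeProp),
                       stats::setNames(config$privateTypeProp, pt))
        }
        datasets[[sp]] <- .simulate_dataset(config, u, prof, dataset_id = sp,
                                            species = sp, type_props = props)
    }
    list(datasets = datasets, orthology = .panel_orthology(config, u),
         genes = u, profiles = prof, config = config)
}

#' Generate the regeneration time-course series
#'
#' Datasets labelled by timepoint for a single (axolotl-like) species. The
#' AEC type expresses a configured fraction of the AER program (the
#' FGF-ligand-like tail of the program is dropped), and a fraction
#' `ctProgramFraction` of connective-tissue cells additionally carries a
#' partial AER program headed by the designated epithelial markers.
#'
#' @param config a [synthConfig()].
#' @return as [generateDevelopmentPanel()], with one dataset per timepoint.
#' @export
generateRegenerationSeries <- function(config) {
    .validate_config(config)
    if (config$ctProgramFraction > 1)
        stop("ctProgramFraction must not exceed 1")
    u <- .gene_universe(config)
    set.seed(config$seed)
    regen_types <- c(AEC = 0.20, BasalEctoderm = 0.15, CT = 0.40, Muscle = 0.25)
    prof <- .type_profiles(config, u, names(regen_types))
    sp <- config$species[1]
    datasets <- list()
    for (tp in config$timepoints) {
        id <- paste0(sp, "_", tp)
        datasets[[id]] <- .simulate_dataset(config, u, prof, dataset_id = id,
                                            species = sp,
                                            type_props = regen_types,
                                            regen = TRUE)
    }
    list(datasets = datasets, genes = u, profiles = prof, config = config)
}

#' Generate a synthetic spatial (Visium-style) section
#'
#' Spots on a regular grid are partitioned into three contiguous domains:
#' intact connective tissue, a blastema enriched for program-carrying CT
#' cells, and an AEC rim at the distal edge. Each spot's counts are the sum
#' of the counts of `cellsPerSpot` synthetic single cells sampled from its
#' domain's type mixture.
#'
#' @param config a [synthConfig()].
#' @return a list with `spots` (a `SingleCellExperiment` over spots; the
#'   spot truth table, including the domain label, is its `colData`),
#'   `positions` (Visium-style `tissue_positions` table), `cells` (the
#'   constituent single cells with their spot assignment) and `config`.
#' @export
generateSpatialSection <- function(config) {
    .validate_config(config)
    if (config$gridNcol < 8 || config$gridNrow < 2)
        stop("grid too small to host the three tissue domains (need >= 2 x 8)")
    u <- .gene_universe(config)
    set.seed(config$seed)
    regen_types <- c(AEC = 0.20, BasalEctoderm = 0.15, CT = 0.40, Muscle = 0.25)
    prof <- .type_profiles(config, u, names(regen_types))
    sp <- config$species[1]

    nr <- config$gridNrow
    nc <- config$gridNcol
    col_of <- rep(seq_len(nc), each = nr)
    row_of <- rep(seq_len(nr), times = nc)
    domain <- ifelse(col_of > nc - 2, "AEC_rim",
                     ifelse(col_of > nc - 8, "blastema", "intact_CT"))
    n_spots <- nr * nc
    spot_ids <- sprintf("spot%04d", seq_len(n_spots))

    mixtures <- list(
        intact_CT = c(CT = 0.7, Muscle = 0.3),
        blastema = c(CT_program = 0.5, CT = 0.3, Muscle = 0.2),
        AEC_rim = c(AEC = 0.7, BasalEctoderm = 0.3)
    )

    # generate constituent cells: expected means at symbol level
    n_cells <- n_spots * config$cellsPerSpot
    cell_type_raw <- character(n_cells)
    cell_spot <- rep(spot_ids, each = config$cellsPerSpot)
    for (s in seq_len(n_spots)) {
        mix <- mixtures[[domain[s]]]
        idx <- (s - 1L) * config$cellsPerSpot + seq_len(config$cellsPerSpot)
        cell_type_raw[idx] <- sample(names(mix), config$cellsPerSpot,
                                     replace = TRUE, prob = mix)
    }
    carrier <- cell_type_raw == "CT_program"
    cell_type <- ifelse(carrier, "CT", cell_type_raw)

    lam <- t(prof)[, cell_type, drop = FALSE]
    ct_sub <- u$program[seq_len(round(config$ctProgramOverlap * length(u$program)))]
    if (any(carrier))
        lam[ct_sub, carrier] <- lam[ct_sub, carrier] * exp(config$aerEffect)
    other_private <- unlist(u$private[setdiff(names(u$private), sp)])
    keep <- setdiff(seq_len(config$nGenes), other_private)
    lam <- lam[keep, , drop = FALSE]
    rownames(lam) <- u$symbols[keep]
    sf <- stats::rlnorm(n_cells, meanlog = -config$depthSigma^2 / 2,
                        sdlog = config$depthSigma)
    lam <- sweep(lam, 2, colSums(lam), "/")
    lam <- sweep(lam, 2, config$depthMean * sf, "*")
    cell_counts <- matrix(stats::rnbinom(length(lam), mu = as.vector(lam),
                                         size = 1 / config$nbDispersion),
                          nrow = nrow(lam), dimnames = dimnames(lam))
    cell_ids <- sprintf("cell%05d", seq_len(n_cells))
    colnames(cell_counts) <- cell_ids

    spot_counts <- sapply(seq_len(n_spots), function(s) {
        idx <- (s - 1L) * config$cellsPerSpot + seq_len(config$cellsPerSpot)
        rowSums(cell_counts[, idx, drop = FALSE])
    })
    colnames(spot_counts) <- spot_ids

    spot_truth <- DataFrame(
        spot_id = spot_ids, species = sp, dataset_id = "visium_section",
        domain = domain,
        n_program_cells = vapply(seq_len(n_spots), function(s) {
            idx <- (s - 1L) * config$cellsPerSpot + seq_len(config$cellsPerSpot)
            sum(carrier[idx])
        }, 0L)
    )
    spots <- SingleCellExperiment(assays = list(counts = spot_counts),
                                  colData = spot_truth)
    metadata(spots)$dataset <- "visium_section"
    metadata(spots)$species <- sp

    cells <- SingleCellExperiment(
        assays = list(counts = cell_counts),
        colData = DataFrame(cell_id = cell_ids, spot_id = cell_spot,
                            true_type = cell_type,
                            carries_program = carrier | cell_type == "AEC")
    )
    positions <- data.frame(
        barcode = spot_ids, in_tissue = 1L,
        array_row = row_of, array_col = col_of,
        pxl_row_in_fullres = row_of * 100L, pxl_col_in_fullres = col_of * 100L
    )
    list(spots = spots, positions = positions, cells = cells, config = config)
}

#' Write a generated panel to disk in 10x-style text formats
#'
#' Each dataset becomes an MTX bundle directory plus a `truth.tsv`; the
#' configuration is written as YAML and the orthology table (if present) as
#' TSV.
#'
#' @param panel output of a `generate*` function.
#' @param dir output directory.
#' @export
writePanel <- function(panel, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(panel$datasets)) {
        sub <- file.path(dir, nm)
        writeCountsMTX(panel$datasets[[nm]], sub)
        writeTruthTable(as.data.frame(colData(panel$datasets[[nm]])),
                        file.path(sub, "truth.tsv"))
    }
    if (!is.null(panel$orthology))
        writeOrthology(panel$orthology, file.path(dir, "orthology.tsv"))
    writeSynthConfig(panel$config, file.path(dir, "config.yaml"))
    invisible(dir)
}

#' Simulate a nonnegative matrix with disjoint planted programs
#'
#' Builds a cells x genes count matrix in which each cell uses exactly one
#' of `nPrograms` disjoint gene programs on top of a low background, with
#' negative binomial noise — the benchmark input for [consensusNMF()]
#' rank selection and module-recovery checks.
#'
#' @param nCells,nGenes matrix dimensions.
#' @param nPrograms number of disjoint programs.
#' @param genesPerProgram program block size.
#' @param background background mean.
#' @param programMean mean of program genes in cells using the program.
#' @param dispersion negative binomial dispersion phi.
#' @param seed integer seed.
#' @return list with `counts` (cells x genes), `program` (per-cell program
#'   index) and `programGenes` (list of gene-name vectors).
#' @export
simulateProgramMatrix <- function(nCells = 300L, nGenes = 150L, nPrograms = 3L,
                                  genesPerProgram = 30L, background = 0.5,
                                  programMean = 10, dispersion = 0.25,
                                  seed = 1L) {
    set.seed(.check_seed(seed))
    genes <- sprintf("G%04d", seq_len(nGenes))
    if (nPrograms * genesPerProgram > nGenes)
        stop("programs do not fit in the gene universe")
    prog_genes <- split(seq_len(nPrograms * genesPerProgram),
                        rep(seq_len(nPrograms), each = genesPerProgram))
    program <- rep(seq_len(nPrograms), length.out = nCells)
    mu <- matrix(background, nrow = nCells, ncol = nGenes)
    for (p in seq_len(nPrograms))
        mu[program == p, prog_genes[[p]]] <- programMean
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = 1 / dispersion),
                     nrow = nCells,
                     dimnames = list(sprintf("cell%04d", seq_len(nCells)), genes))
    list(counts = counts, program = program,
         programGenes = lapply(prog_genes, function(i) genes[i]))
}
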
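#' Pipeline configuration
#'
#' Bundles every stage's parameters with defaults equal to the published
#' values: length filter 25-60 nt, Phred > 20, clustering identity 0.85,
#' edge-weight fraction 0.05, mini-array alpha 0.01 with abundance
#' thresholds 100 (one spacer) and 20 (two spacers), protospacer word
#' size 8 at identity 0.85, all-vs-all identity 0.7, conservation window
#' 50, and 10000 simulated spacers for the coincidence test.
#'
#' Input is either a simulated community (`simulate = TRUE`, using
#' `community` and `read_params`) or a manifest of FASTQ files
#' (`samples`, named `sample_id -> path`).
#'
#' @param outdir Output directory for stage artifacts.
#' @param simulate Generate the input community and reads (default TRUE).
#' @param community A [community_config()] (when simulating).
#' @param read_params A [read_sim_params()] (when simulating).
#' @param samples Named character vector of FASTQ paths (when not
#'   simulating).
#' @param repeat_consensus Named IUPAC strings, one per repeat type.
#' @param primers Character vector of primer motifs to scan.
#' @param extraction An [extraction_params()].
#' @param cluster_threshold Clustering identity threshold.
#' @param edge_fraction,edge_mode Chimera-filter settings (see
#'   [filter_chimeric_edges()]).
#' @param mini_alpha,mini_thresholds Mini-array call settings.
#' @param target_genomes Optional named character vector of genome
#'   sequences (or a FASTA path) for protospacer search.
#' @param min_identity,word_size Protospacer matching parameters.
#' @param assembly_min_identity All-vs-all overlap identity threshold.
#' @param stages Stages to run, in order, from `"simulate"`,
#'   `"extract"`, `"cluster"`, `"graph"`, `"mini"`, `"protospacer"`,
#'   `"assemble"`.
#' @param seed Master seed (overrides the seeds in `community` /
#'   `read_params` when set).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            simulate = TRUE,
                            community = community_config(),
                            read_params = read_sim_params(),
                            samples = NULL,
                            repeat_consensus = NULL,
                            primers = NULL,
                            extraction = extraction_params(),
                            cluster_threshold = 0.85,
                            edge_fraction = 0.05,
                            edge_mode = "either",
                            mini_alpha = 0.01,
                            mini_thresholds = c(`1` = 100L, `2` = 20L),
                            target_genomes = NULL,
                            min_identity = 0.85,
                            word_size = 8L,
                            assembly_min_identity = 0.7,
                            stages = c("simulate", "extract", "cluster",
                                       "graph", "mini", "protospacer",
                                       "assemble"),
                            seed = NULL) {
  if (!simulate && "extract" %in% stages) {
    if (is.null(samples) || is.null(names(samples))) {
      stop("configuration error: non-simulated runs need a named ",
           "sample -> FASTQ manifest")
    }
    missing <- samples[!file.exists(samples)]
    if (length(missing)) {
      stop("configuration error: FASTQ file(s) not found: ",
           paste(missing, collapse = ", "))
    }
    if (is.null(repeat_consensus)) {
      stop("configuration error: repeat_consensus required for FASTQ input")
    }
  }
  if (!is.null(seed)) {
    community$seed <- as.integer(seed)
    read_params$seed <- as.integer(seed) + 1L
  }
  structure(list(
    outdir = outdir, simulate = simulate, community = community,
    read_params = read_params, samples = samples,
    repeat_consensus = repeat_consensus, primers = primers,
    extraction = extraction, cluster_threshold = cluster_threshold,
    edge_fraction = edge_fraction, edge_mode = edge_mode,
    mini_alpha = mini_alpha, mini_thresholds = mini_thresholds,
    target_genomes = target_genomes, min_identity = min_identity,
    word_size = word_size,
    assembly_min_identity = assembly_min_identity,
    stages = stages, seed = seed
  ), class = "pipeline_config")
}

.stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

# rebuild the cluster state written by the cluster stage, so later
# stages can resume from TSV artifacts alone
.load_cluster_artifacts <- function(outdir) {
  cf <- file.path(outdir, "clusters.tsv")
  af <- file.path(outdir, "assignment.tsv")
  if (!file.exists(cf) || !file.exists(af)) {
    stop("cannot resume: cluster artifacts not found in ", outdir)
  }
  tab <- read_tsv(cf)
  asg <- read_tsv(af)
  meta <- c("cluster_id", "centroid", "n_members", "total")
  ab <- as.matrix(tab[, setdiff(names(tab), meta), drop = FALSE])
  rownames(ab) <- tab$cluster_id
  structure(list(
    clusters = tab[, meta],
    abundance = ab,
    assignment = stats::setNames(asg$cluster_id, asg$sequence),
    obs_cluster = NULL,
    threshold = NA_real_
  ), class = "spacer_clusters")
}

.resume_tables <- function(res, outdir) {
  if (is.null(res$spacers)) {
    fp <- file.path(outdir, "spacers.tsv")
    if (!file.exists(fp)) stop("cannot resume: ", fp, " not found")
    res$spacers <- read_tsv(fp)
  }
  if (is.null(res$pairs)) {
    fp <- file.path(outdir, "pairs.tsv")
    if (!file.exists(fp)) stop("cannot resume: ", fp, " not found")
    res$pairs <- read_tsv(fp)
  }
  res
}

#' Run the CRISPRome analysis pipeline
#'
#' Executes the configured stages in order (simulate -> extract ->
#' cluster -> graph -> mini -> protospacer -> assemble), writing each
#' stage's tables as TSV under `config$outdir` and returning the
#' in-memory results. A manifest of every written artifact with its MD5
#' content hash is written last, so two runs with identical inputs and
#' seeds can be compared byte-for-byte.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `crisprome_pipeline`: list of per-stage
#'   results plus `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)
  artifacts <- character(0)
  add_artifact <- function(path) artifacts <<- c(artifacts, path)
  st <- config$stages

  # ---- simulate ----
  if ("simulate" %in% st && config$simulate) {
    community <- generate_community(config$community)
    reads <- generate_amplicon_reads(community, config$read_params)
    res$community <- community
    res$reads <- reads
    fq <- file.path(config$outdir, "sample1.fastq")
    write_fastq(reads$reads, fq)
    add_artifact(fq)
    add_artifact(write_tsv(reads$truth,
                           file.path(config$outdir, "truth_spacers.tsv")))
    add_artifact(write_tsv(reads$pair_truth,
                           file.path(config$outdir, "truth_pairs.tsv")))
    add_artifact(write_fasta(community_fasta(community),
                             file.path(config$outdir, "community.fasta")))
    config$samples <- c(sample1 = fq)
    config$repeat_consensus <- config$community$repeat_consensus_by_type
    if (is.null(config$primers)) {
      config$primers <- c(config$read_params$primer_fwd,
                          revcomp(config$read_params$primer_rev))
    }
    .stage_log("simulate", "%d reads from %d arrays",
               nrow(reads$reads), length(community$arrays))
  }

  # ---- extract ----
  if ("extract" %in% st) {
    if (is.null(config$samples)) stop("no samples to extract from")
    primer_motifs <- lapply(seq_along(config$primers), function(i) {
      degenerate_motif(paste0("primer", i), config$primers[i])
    })
    spacers <- list(); pairs <- list()
    for (sid in names(config$samples)) {
      reads_df <- read_fastq(config$samples[[sid]])
      for (ty in names(config$repeat_consensus)) {
        ex <- extract_sample(
          reads_df, degenerate_motif(ty, config$repeat_consensus[[ty]]),
          primers = primer_motifs, params = config$extraction,
          sample_id = sid
        )
        spacers[[paste(sid, ty)]] <- ex$spacers
        pairs[[paste(sid, ty)]] <- ex$pairs
        .stage_log("extract", "%s/%s: %d reads, %d spacers kept, %d filtered",
                   sid, ty, ex$summary$reads_scanned,
                   ex$summary$spacers_kept, ex$summary$spacers_filtered)
      }
    }
    res$spacers <- do.call(rbind, c(spacers, list(make.row.names = FALSE)))
    res$pairs <- do.call(rbind, c(pairs, list(make.row.names = FALSE)))
    add_artifact(write_tsv(res$spacers,
                           file.path(config$outdir, "spacers.tsv")))
    add_artifact(write_tsv(res$pairs,
                           file.path(config$outdir, "pairs.tsv")))
  }

  # ---- cluster ----
  if ("cluster" %in% st) {
    res <- .resume_tables(res, config$outdir)
    cl <- cluster_spacers(res$spacers$sequence,
                          samples = res$spacers$sample_id,
                          threshold = config$cluster_threshold)
    res$clusters <- cl
    add_artifact(write_tsv(cbind(cl$clusters, cl$abundance),
                           file.path(config$outdir, "clusters.tsv")))
    add_artifact(write_tsv(
      data.frame(sequence = names(cl$assignment),
                 cluster_id = unname(cl$assignment)),
      file.path(config$outdir, "assignment.tsv")
    ))
    div <- do.call(rbind, lapply(colnames(cl$abundance), function(s) {
      counts <- cl$abundance[, s]
      counts <- counts[counts > 0]
      sc <- shannon_chao(counts)
      data.frame(sample_id = s, n_clusters = sc$n_clusters,
                 goods_C = goods_coverage(counts),
                 shannon_H = sc$shannon_H, chao1 = sc$chao1,
                 n_rare = sc$n_rare)
    }))
    res$diversity <- div
    add_artifact(write_tsv(div, file.path(config$outdir,
                                          "diversity.tsv")))
    .stage_log("cluster", "%d observations -> %d clusters",
               length(cl$obs_cluster), nrow(cl$clusters))
  }

  # ---- graph ----
  run_graph_stage <- function(res) {
    res <- .resume_tables(res, config$outdir)
    if (is.null(res$clusters)) {
      res$clusters <- .load_cluster_artifacts(config$outdir)
    }
    cl <- res$clusters
    pair_clusters <- data.frame(
      first = unname(cl$assignment[res$pairs$first]),
      second = unname(cl$assignment[res$pairs$second])
    )
    g <- build_pair_graph(pair_clusters, nodes = cl$clusters$cluster_id)
    filt <- filter_chimeric_edges(g, fraction = config$edge_fraction,
                                  mode = config$edge_mode)
    paths <- reconstruct_paths(filt$graph)
    ecc <- node_eccentricity(filt$graph)
    res$pair_graph <- g
    res$filtered <- filt
    res$paths <- paths
    res$eccentricity <- ecc
    add_artifact(write_tsv(filt$report,
                           file.path(config$outdir, "edges.tsv")))
    path_lines <- vapply(paths$paths, paste, character(1),
                         collapse = ",")
    writeLines(path_lines, file.path(config$outdir, "paths.txt"))
    add_artifact(file.path(config$outdir, "paths.txt"))
    add_artifact(write_tsv(ecc, file.path(config$outdir,
                                          "eccentricity.tsv")))
    .stage_log("graph", "%d edges (%d removed as chimeric), %d paths",
               nrow(g$edges), sum(filt$report$removed),
               length(paths$paths))
    res
  }
  if ("graph" %in% st) res <- run_graph_stage(res)

  # ---- mini ----
  if ("mini" %in% st) {
    if (is.null(res$paths)) res <- run_graph_stage(res)
    pp <- estimate_pair_probability(res$spacers)
    ab <- stats::setNames(res$clusters$clusters$total,
                          res$clusters$clusters$cluster_id)
    calls <- call_mini_arrays(res$paths, res$eccentricity, ab, pp,
                              alpha = config$mini_alpha,
                              thresholds = config$mini_thresholds)
    res$pair_probability <- pp
    res$mini_calls <- calls
    add_artifact(write_tsv(as.data.frame(calls),
                           file.path(config$outdir, "mini_arrays.tsv")))
    .stage_log("mini", "p = %.3f; %d candidates, %d called complete",
               pp$p, nrow(calls), sum(calls$complete))
  }

  # ---- protospacer ----
  has_targets <- !is.null(config$target_genomes) ||
    (!is.null(res$community) && length(res$community$viruses) > 0)
  if ("protospacer" %in% st && has_targets) {
    if (is.null(res$clusters)) {
      res$clusters <- .load_cluster_artifacts(config$outdir)
    }
    genomes <- config$target_genomes
    if (is.null(genomes)) {
      genomes <- vapply(res$community$viruses, `[[`, character(1),
                        "genome")
    }
    if (is.character(genomes) && length(genomes) == 1L &&
        file.exists(genomes)) {
      genomes <- read_fasta(genomes)
    }
    centroids <- stats::setNames(res$clusters$clusters$centroid,
                                 res$clusters$clusters$cluster_id)
    hits <- do.call(rbind, lapply(names(genomes), function(gid) {
      find_protospacers(centroids, genomes[[gid]], genome_id = gid,
                        min_identity = config$min_identity,
                        word_size = config$word_size)
    }))
    res$protospacers <- hits
    add_artifact(write_tsv(hits,
                           file.path(config$outdir, "protospacers.tsv")))
    if (!is.null(res$mini_calls)) {
      mini_cl <- unlist(strsplit(
        res$mini_calls$cluster_ids[res$mini_calls$complete], ","))
      src <- stats::setNames(
        ifelse(res$clusters$clusters$cluster_id %in% mini_cl, "mini",
               "long"),
        res$clusters$clusters$cluster_id
      )
      res$immunity <- immunity_contributions(hits,
                                             res$clusters$abundance, src)
      add_artifact(write_tsv(res$immunity,
                             file.path(config$outdir, "immunity.tsv")))
    }
    .stage_log("protospacer", "%d hits in %d genome(s)", nrow(hits),
               length(genomes))
  }

  # ---- assemble ----
  if ("assemble" %in% st) {
    if (is.null(res$clusters)) {
      res$clusters <- .load_cluster_artifacts(config$outdir)
    }
    centroids <- stats::setNames(res$clusters$clusters$centroid,
                                 res$clusters$clusters$cluster_id)
    if (length(centroids) >= 2) {
      mg <- all_vs_all_matches(centroids,
                               min_identity = config$assembly_min_identity,
                               word_size = config$word_size)
      tc <- tile_contigs(mg, word_size = config$word_size)
      res$match_graph <- mg
      res$contigs <- tc
      multi <- Filter(function(ct) nrow(ct$layout) > 1, tc$contigs)
      if (length(multi)) {
        fa <- stats::setNames(
          vapply(multi, `[[`, character(1), "consensus"),
          vapply(multi, `[[`, character(1), "contig_id")
        )
        add_artifact(write_fasta(fa, file.path(config$outdir,
                                               "contigs.fasta")))
      }
      lay <- do.call(rbind, lapply(tc$contigs, function(ct) {
        cbind(contig_id = ct$contig_id, ct$layout)
      }))
      add_artifact(write_tsv(lay, file.path(config$outdir,
                                            "contig_layout.tsv")))
      .stage_log("assemble", "%d match edges, %d multi-spacer contigs",
                 nrow(mg$edges), length(multi))
    }
  }

  manifest <- data.frame(
    file = basename(artifacts),
    md5 = unname(tools::md5sum(artifacts))
  )
  write_tsv(manifest, file.path(config$outdir, "manifest.tsv"))
  res$manifest <- manifest
  class(res) <- "crisprome_pipeline"
  res
}

#' @export
print.crisprome_pipeline <- function(x, ...) {
  cat("CRISPRome pipeline run:", x$config$outdir, "\n")
  cat("  artifacts:", nrow(x$manifest), "\n")
  if (!is.null(x$clusters)) {
    cat("  clusters:", nrow(x$clusters$clusters), "\n")
  }
  if (!is.null(x$mini_calls)) {
    cat("  mini-arrays called:", sum(x$mini_calls$complete), "\n")
  }
  invisible(x)
}

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are
#' parsed as numbers where possible, comma-separated values become
#' vectors. Used by the command-line front-end.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}
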
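# annohub

Biomedical knowledge is scattered across resources that each publish their
own files, formats and release schedules: gene catalogs, pathway databases,
variant and chemical annotation sets. Anyone who wants "everything known
about entity X" in one place ends up writing the same plumbing — download
each source, parse it, notice when it changed, stitch records together by a
shared identifier, and put a queryable service in front of the result.

`annohub` packages that plumbing as a small, fully offline-testable data
hub for R. Each data source is a **plugin**: a directory with a
`manifest.json` (where the payload lives, which parser turns it into
documents, optionally a cron schedule and a merge priority) and the parser
script itself. The hub then runs a five-stage pipeline:

1. **dump** — fetch the payload into a versioned release folder,
   `<data_root>/<source>/<release>/`. Release identity is the SHA-256 of
   the content, so an unchanged source is never re-ingested;
2. **upload** — run the plugin's parser, validate every emitted document
   (non-empty `_id`, clean keys, finite leaves), and load the survivors
   into a per-source JSON-lines store, replacing the namespace wholesale;
3. **build** — merge the selected sources into one document per entity
   identifier. Each source's body is namespaced under its own top-level
   key, which makes the merge total, lossless and order-invariant.
   *Root sources* gate membership: if any are configured, an `_id` must
   occur in at least one of them to enter the corpus;
4. **inspect / index** — profile every field path's observed types,
   derive a typed mapping through a small type lattice
   (`integer ⊔ float = float`, anything with a string becomes `keyword`,
   subtree-vs-scalar is a conflict and is excluded), and build an embedded
   inverted index over exactly the mapped paths. Unmapped fields stay in
   the stored documents — retrievable by id, invisible to queries;
5. **serve** — expose the index over HTTP with annotation-style endpoints:
   `GET /{entity}/{id}`, `GET /query`, `POST /query` (batch, up to 1000
   ids), `GET /metadata`, `GET /metadata/fields`, `GET /status`.

A deterministic fixture generator ships with the package so the whole
pipeline — including identifier overlap, mixed-type fields and
object/scalar conflicts — can be exercised without touching the network.

## Worked example

`fixture_fix1()` writes the two-source demonstration corpus: source
`alpha` (TSV) carries `g1 {symbol:"CDK2", taxid:9606}` and
`g2 {symbol:"TP53", taxid:9606}`; source `beta` (JSON lines) carries
`g1 {pathway:["cell_cycle","dna_repair"]}` and
`g3 {pathway:["apoptosis"]}`.

```r
library(annohub)
hub <- tempfile("hub")
plugins <- fixture_fix1(tempfile("plugins"))

reg <- registry()
for (p in plugins$plugin_dirs) reg <- register_source(reg, load_manifest(p))

store <- doc_store_jsonl(hub)
for (nm in registry_names(reg)) {
  d <- registry_get(reg, nm)
  dump <- dump_source(d, hub)
  print(upload_source(d, dump$release, store, hub))
}
#> <upload alpha/2026-09-30T15-48-18-bf2f149c6d07> accepted 2, rejected 0, duplicates collapsed 0
#> <upload beta/2026-09-30T15-48-18-f0a5b373a6a3> accepted 2, rejected 0, duplicates collapsed 0

cfg <- build_config("demo", c("alpha", "beta"), root_sources = "alpha")
build <- run_build(cfg, store, data_root = hub, registry = reg)
print(build)
#> <build demo.20260930154818> 2 merged document(s), 1 root-excluded, 2 source(s)
```

Two documents merge (`g1`, `g2`) because `alpha` is the root source and
`g3` appears only in `beta`. Inspection derives the index mapping
automatically:

```r
mapping <- generate_mapping(inspect_documents(unname(build$merged)))
print(mapping)
#> <mapping> 5 path(s), 0 excluded
#>   alpha: object
#>   alpha.symbol: keyword
#>   alpha.taxid: integer
#>   beta: object
#>   beta.pathway: keyword

index <- build_index(build, mapping)
res <- execute_query(index, "alpha.taxid:>9000 AND cdk2")
print(res)
#> <query result> total 1, showing 1 (from 0)
cat(doc_to_json(res$hits[[1]]))
#> {"_id":"g1","alpha":{"symbol":"CDK2","taxid":9606},"beta":{"pathway":["cell_cycle","dna_repair"]}}
```

Only `g1` satisfies both the numeric range on `alpha.taxid` and the bare
term `cdk2` (bare terms search every keyword field, case-insensitively).
The hit carries both source namespaces of `g1`.

The same walk is available from a shell via the `annohub` console
(`exec/annohub`): `register`, `dump`, `upload`, `build`, `inspect`,
`index`, `serve` and `status` subcommands, each a thin wrapper over the
functions above.

## Vignette

`vignettes/annohub-methods.Rmd` documents the merge and mapping semantics,
the query grammar, every tunable default, what the synthetic fixtures do
and do not emulate, and the package's known limitations.
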
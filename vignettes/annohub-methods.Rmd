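---
title: "annohub: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{annohub: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents how `annohub` works and why it works that way:
the data model, the semantics of each pipeline stage, every tunable
default, what the synthetic fixtures do and do not emulate, and the
package's known limitations.

## The data model

The unit of everything is the **annotation document**: a JSON-style tree
keyed by a unique string identifier `_id`. In R, a document is a named
list whose inner nodes are named lists (objects) or unnamed lists
(arrays) and whose leaves are length-1 character, integer, double or
logical values. Validation enforces:

* `_id` present, non-empty, at most 512 bytes (a conventional
  search-engine identifier limit), no surrounding whitespace;
* keys non-empty, containing no `"."` (dots are reserved for path
  notation) and not starting with `"$"` — the restrictions common to
  document stores, kept so external backends remain drop-in;
* no `NA`, `NaN` or infinite leaves.

All violations of a document are collected and reported together, so a
parser author sees every problem in one pass. Integer-valued doubles are
left as doubles: the hub never silently coerces types.

Serialization is JSON lines via `jsonlite` with scalars unboxed and
arrays preserved (a one-element array stays an array). The JSON byte
stream is the storage contract: two pipeline runs over the same inputs
produce byte-identical store files, which is what the idempotence tests
assert.

## Plugins and the registry

A data-source plugin is a directory holding `manifest.json` and the
parser script it names. The manifest needs `name`, `location` (`file://`
or `http(s)://` URI) and `parser_ref` (`"unit:callable"`, resolved to
`unit.R` beside the manifest); `schedule`, `priority` and free-form
`metadata` are optional. One plugin feeds exactly one source — the
simplest contract, and nothing in the pipeline needs more.

`parser_ref` is resolved eagerly at registration so a broken plugin
fails immediately rather than at upload time. Re-registering a name
replaces the descriptor (with a logged warning) and preserves
accumulated state; plugin iteration should not require delete commands.

Schedules use standard five-field cron (minute, hour, day-of-month,
month, day-of-week; `7 == 0 ==` Sunday; when both day fields are
restricted a time matches if either does), evaluated at minute
granularity in UTC. `schedule_due()` is a pure function of
`(descriptor, last_run, now)`: no clock is read, which keeps every
scheduling test deterministic. No daemon runs inside the package — the
CLI's `status` marks sources "due" and an external scheduler invokes
`dump`.

## Release detection and dumping

A release is identified by its **content**: the SHA-256 checksum of the
payload (for directories, a checksum over the sorted listing of per-file
checksums). Modification times and HTTP `Last-Modified`/`ETag` headers
are only hints that make tag values sortable and readable — the tag is
`<mtime>-<sha256 prefix>`, and two tags denote the same release exactly
when their checksums agree. Touching a file without changing bytes is
therefore "unchanged", and for header-less HTTP sources the checksum
fallback defines the release. This choice makes release detection
reproducible: it depends on nothing but the bytes.

Dumps are atomic: the payload lands in a temporary folder, checksums are
verified after copying, the `release.json` sidecar (tag, origin,
retrieval time, per-file sizes and checksums) is written, and only then
is the folder renamed into `<data_root>/<source>/<release>/`. A failure
at any point removes the temporary folder, so the release listing is
never half-updated. A testing hook (`options(annohub.copy_fault = ...)`)
injects a fault between file copies to let the tests observe exactly
this property; a genuine mid-copy I/O error cannot be provoked portably.

## Upload semantics

Parsers may return a list of documents or a zero-argument iterator
closure (one document per call, `NULL` at exhaustion); the engine
consumes both through the same iterator interface, so a large source
never has to materialize at once. Upload is **replace-on-upload**: the
(source, release) namespace is rebuilt wholesale, making re-upload
idempotent and builds reproducible; merging across sources is the build
stage's job, not upload's. Within a stream, a repeated `_id` is benign —
the later document wins and the collapse is counted — while an invalid
document is skipped with its ordinal and reasons recorded. A parser
exception aborts the whole release: the staged namespace is discarded
and the store is left exactly as before the call.

## The merge policy

Merging is **source-namespaced**: each source's body is placed under a
top-level key equal to the source name, namespaces sorted by source
name. Three properties fall out by construction, and the test suite
verifies each against brute force:

* *totality* — no conflict-resolution rules are ever needed, because
  payloads cannot collide;
* *order-invariance* — permuting the configured sources changes no
  merged tree;
* *losslessness* — every merged leaf is verbatim a leaf of exactly one
  contributing source document.

Source `priority` is carried through the registry for future field-level
merge policies but deliberately unused by the namespaced merge.
Root-source semantics gate membership: when `root_sources` is non-empty,
an identifier enters the build only if at least one root source carries
it (mirroring how a production gene service keys everything to a
reference identifier namespace); an empty root set admits the union.
Identifier comparison is exact and byte-wise — reconciling aliases
across identifier systems is explicitly out of scope. Merged corpora are
flat one-document-per-entity collections with per-source nesting
retained; the package does not flatten namespaces away.

Build versions are `<config name>.<UTC yyyymmddHHMMSS>` with a `-N`
suffix on same-second collisions. Builds persist atomically
(`merged.jsonl` sorted by `_id`, plus `build.json` metadata).

## Type inspection and the mapping lattice

The inspector streams over a corpus once, profiling each dotted field
path: the multiset of observed types (`string`, `integer`, `float`,
`boolean`, `subtree`), whether the path ever occurred inside a list,
the number of documents containing it, and up to three example values
(for the console report only). Memory is constant in corpus size and
linear in distinct paths. Lists are transparent — they never extend the
path — so a scalar in one document and a list of scalars in another are
the *same* path, mirroring search-engine array semantics; that mix is
not a conflict.

The mapping is derived through a small join lattice:

| observed set | mapped type |
|---|---|
| `{integer}` | `integer` |
| `{float}` or `{integer, float}` | `float` |
| any set containing `string` (no `subtree`) | `keyword` |
| `{boolean}` | `boolean` |
| `boolean` mixed with others | `keyword` |
| `{subtree}` | `object` |
| `subtree` + any scalar | **conflict** — excluded |

The join is commutative, associative and idempotent; the tests verify
the laws exhaustively over all 31 non-empty type subsets. Two deliberate
choices: numeric-looking strings are *not* promoted to numbers (`"9606"`
stays a string — no silent coercion), and strings map to exact-match
`keyword` with lowercase normalization at index and query time rather
than analyzed full text, which keeps query semantics bit-exactly
testable. A conflict excludes only the conflicting path itself, not its
descendants, which remain independently mappable in the embedded
path-based index. Mapping files serialize to an Elasticsearch-7-style
`{"properties": ...}` dialect so an external index adapter could consume
them unchanged; the CLI accepts a hand-edited mapping file, though no
merge-of-edits logic is defined.

## The query engine

Only mapped paths are queryable; every stored document remains
retrievable in full by `_id`, unmapped fields included. That
indexed-versus-stored distinction is observable: a fielded query on an
unmapped or wrongly typed path raises an `unqueryable field` error
naming the path — never a silent empty result.

The grammar is a deliberately minimal, exact-match subset (it makes no
claim about any production system's syntax): `path:value` fielded terms,
`path:>n` / `>=` / `<` / `<=` numeric ranges, bare terms searched across
all keyword paths, trailing-`*` prefix wildcards, uppercase `AND`/`OR`
with `AND` binding tighter, parentheses, double-quoted values, and
implicit `AND` between adjacent expressions. Parse errors carry the
offending character position.

Matching is case-insensitive exact (prefix for wildcards); `AND`
intersects and `OR` unions id sets. Ranking is fully deterministic:
descending per-document primitive-match count (a bare term scores one
per keyword path it matches in the document, sums propagate through
`AND`/`OR`), ties broken by ascending `_id`. Deterministic ranking —
rather than a relevance score — is what makes pagination coherence
provable: concatenating pages of any size reproduces the full ranked
list exactly once. Defaults follow annotation-API convention: page size
10, offset 0, size cap 1000, `size = 0` for count-only queries. A value
typed contrary to the mapping (a string where `integer` is mapped) does
not fail indexing: the document is stored, the value is skipped from the
inverted structures, and the skip is counted in the index's build
report.

The central correctness property is oracle equivalence: `oracle_query()`
evaluates any AST by recursive per-document scan with no index at all,
and the engine's id set must equal the oracle's. The test suite runs
1000 randomized cases (ASTs of depth up to 3 over corpora up to 200
documents); the acceptance script reruns the sweep from a caller-chosen
seed.

## The HTTP service

The service is read-only over one indexed build, with the endpoint
surface of an annotation API: `GET /{entity}/{id}` (with `fields`
projection), `GET /query` (`q`, `fields`, `size`, `from`), `POST /query`
(batch: up to 1000 ids, optional `scopes` to match against mapped paths
instead of `_id`, response aligned with request order and misses marked
`"notfound": true`), `GET /metadata`, `GET /metadata/fields`,
`GET /status`. All errors share one envelope:
`{"success": false, "error": ..., "code": ...}`. The `took` field is
wall-clock milliseconds and excluded from every equality test.

The HTTP layer adds nothing: each response body is a pure function of
the app and the parsed request, dispatched through `handle_request()`,
which tests call directly and compare against the underlying query
functions. The bundled server is a minimal blocking HTTP/1.1 loop over
base-R sockets (one connection at a time, Content-Length framing,
connection closed per response) — deliberately simple, intended for
local use and tests; a production deployment would put a real server in
front of the same handlers. Batch-of-one equals the annotation endpoint
modulo the `"query"` wrapper key, by test.

## Synthetic fixtures

`generate_fixture()` writes complete plugin directories (manifest,
parser, payload in TSV, CSV or JSON lines) whose documents are pure
functions of `(seed, source name, ordinal, field)` through a
counter-based hash — no R RNG state is consumed, so the same spec
regenerates byte-identical payloads and any subset of sources is stable.
Identifier overlap is controlled by offsets into a shared `g<number>`
pool; recipes can add nesting (depth up to 3), list-valued fields,
mixed-type numeric fields (emitted as float or string with a chosen
probability, provably triggering the lattice's `float`/`keyword`
promotions) and object/scalar conflict injection. Ground truth — id
sets, unions, intersections, expected merged ids under any root choice,
expected conflict paths — is computed during generation, never by
re-parsing the files, so pipeline outputs are compared against
construction-time truth.

The canonical preset is a two-source corpus: `alpha` (TSV;
`g1 {symbol:"CDK2", taxid:9606}`, `g2 {symbol:"TP53", taxid:9606}`) and
`beta` (JSON lines; `g1 {pathway:[...]}`, `g3 {pathway:[...]}`), small
enough that every expected number is hand-checkable.

What the fixtures emulate: identifier overlap and root gating, format
heterogeneity, schema drift (mixed types), structural pathologies
(conflicts), benign duplicate ids, parser failures. What they do not:
realistic biological content, corpus scale beyond ~10^5 documents,
network behavior (tests stay on `file://`; `http(s)://` retrieval is
implemented but exercised only through its header/checksum logic),
non-UTF-8 encodings, and malformed payload files beyond what parsers
surface. Green tests therefore demonstrate the hub's *mechanics* —
merging, typing, querying, serving — not robustness to every real-world
feed.

## Validation problem sizes

The checked properties and the sizes they run at, chosen to keep the
default suite fast while leaving the estimates stable: the canonical
fixture pipeline end to end; 210 randomized multi-source merge specs
(2-3 sources, 3-25 documents each, random roots, including source-order
permutations and rebuild determinism) against the set-algebra referee;
inspector-versus-enumeration on corpora up to 100 documents plus the
exhaustive lattice check; 1000 random query cases (25 corpora up to 200
documents, 40 ASTs each) against the linear-scan referee with
pagination-coherence spot checks; dump/upload idempotence and
fault-injection atomicity; and batch/single consistency with the
1000-id cap. `scripts/acceptance.R` reruns the same computations from a
command-line seed and reports each agreement rate with its problem size.

## Known limitations

* One service instance serves one build; reload is a restart.
* No incremental/differential builds: every build is full.
* No relevance scoring, fuzzy matching, aggregations or cursors; the
  grammar is a minimal subset by design.
* No authentication, TLS or rate limiting on the embedded server.
* No resumable or authenticated downloads; `file://` and `http(s)://`
  only.
* Cross-namespace identifier reconciliation (alias mapping between
  identifier systems) is out of scope; merges require byte-equal ids.
* The on-disk index format is private to this backend and not portable
  across package versions.
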
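"""SQLite event store backend.

The R package stores detections, fits and derived features in separate
tables of one SQLite file (plus a meta table with the configuration
snapshot), exchanging rows as CSV. Re-running on the same trace replaces
events by (trace_id, t_start).

Usage:
    sqlite_bridge.py write <db> <meta.json> <detections.csv> <fits.csv> <features.csv>
    sqlite_bridge.py read  <db> <outdir>
"""
import csv
import json
import sqlite3
import sys

SCHEMA_VERSION = "1"

TABLES = {
    "detections": [
        ("event_id", "INTEGER"), ("trace_id", "TEXT"),
        ("t_start", "REAL"), ("t_end", "REAL"),
        ("baseline_mean", "REAL"), ("baseline_sd", "REAL"),
    ],
    "fits": [
        ("event_id", "INTEGER"), ("i_open", "REAL"), ("di_b", "REAL"),
        ("mu", "REAL"), ("sigma", "REAL"), ("beta", "REAL"),
        ("rmse", "REAL"), ("converged", "INTEGER"), ("at_bound", "TEXT"),
    ],
    "features": [
        ("event_id", "INTEGER"), ("dwell_time", "REAL"), ("i_ex", "REAL"),
        ("fs_event", "REAL"), ("loc_valid", "INTEGER"),
        ("overlap_valid", "INTEGER"), ("p_threshold", "REAL"),
    ],
}


def create_schema(con):
    for name, cols in TABLES.items():
        coldef = ", ".join(f"{c} {t}" for c, t in cols)
        con.execute(f"CREATE TABLE IF NOT EXISTS {name} ({coldef})")
    con.execute("CREATE TABLE IF NOT EXISTS meta (key TEXT PRIMARY KEY, value TEXT)")


def read_rows(path):
    with open(path, newline="") as fh:
        return list(csv.DictReader(fh))


def coerce(value, sqltype):
    if value is None or value in ("", "NA"):
        return None
    if sqltype == "INTEGER":
        return int(float(value))
    if sqltype == "REAL":
        return float(value)
    return value


def write(db, meta_path, det_path, fit_path, feat_path):
    con = sqlite3.connect(db)
    try:
        cur = con.execute(
            "SELECT name FROM sqlite_master WHERE type='table' AND name='meta'")
        if cur.fetchone() is not None:
            row = con.execute(
                "SELECT value FROM meta WHERE key='schema_version'").fetchone()
            if row is not None and row[0] != SCHEMA_VERSION:
                sys.stderr.write(
                    f"schema version mismatch: store has {row[0]}, code expects "
                    f"{SCHEMA_VERSION}; export the old store to CSV and re-import\n")
                return 2
        create_schema(con)
        with open(meta_path) as fh:
            meta = json.load(fh)
        meta["schema_version"] = SCHEMA_VERSION
        for key, value in meta.items():
            con.execute(
                "INSERT INTO meta (key, value) VALUES (?, ?) "
                "ON CONFLICT(key) DO UPDATE SET value=excluded.value",
                (key, value if isinstance(value, str) else json.dumps(value)))
        detections = read_rows(det_path)
        # idempotent re-run: replace by (trace_id, t_start)
        for row in detections:
            old = con.execute(
                "SELECT event_id FROM detections WHERE trace_id=? AND t_start=?",
                (row["trace_id"], float(row["t_start"]))).fetchall()
            for (eid,) in old:
                for name in TABLES:
                    con.execute(f"DELETE FROM {name} WHERE event_id=?", (eid,))
        for name, path in (("detections", det_path), ("fits", fit_path),
                           ("features", feat_path)):
            cols = TABLES[name]
            rows = read_rows(path)
            placeholders = ", ".join("?" for _ in cols)
            names = ", ".join(c for c, _ in cols)
            for row in rows:
                con.execute(
                    f"INSERT INTO {name} ({names}) VALUES ({placeholders})",
                    [coerce(row.get(c), t) for c, t in cols])
        con.commit()
        print(len(detections))
        return 0
    finally:
        con.close()


def read(db, outdir):
    con = sqlite3.connect(db)
    try:
        row = con.execute(
            "SELECT value FROM meta WHERE key='schema_version'").fetchone()
        if row is not None and row[0] != SCHEMA_VERSION:
            sys.stderr.write(
                f"schema version mismatch: store has {row[0]}, code expects "
                f"{SCHEMA_VERSION}\n")
            return 2
        for name, cols in TABLES.items():
            out = f"{outdir}/{name}.csv"
            with open(out, "w", newline="") as fh:
                writer = csv.writer(fh)
                writer.writerow([c for c, _ in cols])
                order = "ORDER BY event_id"
                for r in con.execute(
                        f"SELECT {', '.join(c for c, _ in cols)} "
                        f"FROM {name} {order}"):
                    writer.writerow(["" if v is None else v for v in r])
        with open(f"{outdir}/meta.json", "w") as fh:
            json.dump(dict(con.execute("SELECT key, value FROM meta")), fh)
        return 0
    finally:
        con.close()


def main(argv):
    if len(argv) >= 2 and argv[1] == "write" and len(argv) == 7:
        return write(*argv[2:])
    if len(argv) >= 2 and argv[1] == "read" and len(argv) == 4:
        return read(*argv[2:])
    sys.stderr.write(__doc__)
    return 1


if __name__ == "__main__":
    sys.exit(main(sys.argv))
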
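"""Tiny xlsx bridge used by the R exporters.

write: read a JSON sheet description and emit an .xlsx workbook.
read:  dump an .xlsx workbook back to the same JSON shape (all cells as
       strings) so R tests can compare cell values across formats.
"""
import json
import sys

import openpyxl


def write(json_path, xlsx_path):
    with open(json_path, encoding="utf-8") as fh:
        spec = json.load(fh)
    wb = openpyxl.Workbook()
    wb.remove(wb.active)
    for sheet in spec["sheets"]:
        ws = wb.create_sheet(title=sheet["name"])
        ws.append([str(c) for c in sheet["columns"]])
        for row in sheet["rows"]:
            ws.append([str(c) for c in row])
    wb.save(xlsx_path)


def read(xlsx_path):
    wb = openpyxl.load_workbook(xlsx_path, read_only=True)
    sheets = []
    for name in wb.sheetnames:
        ws = wb[name]
        rows = [["" if c is None else str(c) for c in row]
                for row in ws.iter_rows(values_only=True)]
        header = rows[0] if rows else []
        sheets.append({"name": name, "columns": header, "rows": rows[1:]})
    json.dump({"sheets": sheets}, sys.stdout)


if __name__ == "__main__":
    mode = sys.argv[1]
    if mode == "write":
        write(sys.argv[2], sys.argv[3])
    elif mode == "read":
        read(sys.argv[2])
    else:
        sys.exit("usage: xlsx_io.py write <json> <xlsx> | read <xlsx>")
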